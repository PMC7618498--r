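# Calcium-imaging encoding analysis: zF standardization, saccade-triggered
# d-prime with a permutation null, the 33-regressor CIRF design, OLS
# hyperparameter search, ridge regression with 10-fold cross-validation on
# contiguous blocks, circular-permutation unique-variance attribution, and
# the three-criterion oculomotor-tuned classification.

#' Standardize fluorescence to zF
#'
#' Frames whose motion error exceeds 5 um are replaced by linear
#' interpolation from neighbouring good frames. Each ROI is then baseline
#' subtracted (50th percentile) and divided by the high-frequency noise SD of
#' the baseline-subtracted trace, estimated with the robust first-difference
#' estimator median(|diff x|) / (sqrt(2) * qnorm(0.75)). Zero-noise ROIs are
#' floored at machine epsilon and flagged in \code{attr(, "zero_noise")};
#' zF is invariant to affine rescaling of the raw fluorescence.
#'
#' @param fset a \linkS4class{FluorescenceSet} with >= 100 frames.
#' @param motion_threshold_um interpolation threshold (default 5 um).
#' @return the FluorescenceSet with assay \code{"zF"} added.
#' @export
computeZF <- function(fset, motion_threshold_um = 5) {
  F <- SummarizedExperiment::assay(fset, "F")
  if (ncol(F) < 100) stop("need at least 100 frames")
  bad <- motionError(fset) > motion_threshold_um
  if (all(bad)) stop("all frames exceed the motion-error threshold")
  idx <- seq_len(ncol(F))
  Z <- F
  zero_noise <- logical(nrow(F))
  for (r in seq_len(nrow(F))) {
    x <- F[r, ]
    if (any(bad))
      x[bad] <- approx(idx[!bad], x[!bad], xout = idx[bad], rule = 2)$y
    b <- median(x)
    s <- noiseSD(x)
    if (s <= 0) { s <- .Machine$double.eps; zero_noise[r] <- TRUE }
    Z[r, ] <- (x - b) / s
  }
  SummarizedExperiment::assay(fset, "zF") <- Z
  attr(fset, "zero_noise") <- which(zero_noise)
  fset
}

# Frame-index pre/post windows for event-triggered statistics.
eventWindows <- function(rate_hz, pre_s = 1, post_s = 2) {
  list(npre = max(1L, round(pre_s * rate_hz)),
       npost = max(1L, round(post_s * rate_hz)))
}

#' Saccade-triggered d-prime
#'
#' d' = (mu_post - mu_pre) / sqrt((var_post + var_pre)/2), with the mean and
#' variance pooled across time points and event instances: the post window is
#' 2 s from saccade onset, the pre window the 1 s before onset. Events whose
#' windows leave the recording are dropped. When both variances are zero, d'
#' is 0 for equal means and clipped to +-100 otherwise (flagged).
#'
#' @param zf_roi one ROI's zF vector.
#' @param frame_t frame times (s).
#' @param onsets_s saccade onset times of one type (>= 2 required).
#' @return scalar d' (attribute \code{"clipped"} set when degenerate).
#' @export
saccadeDprime <- function(zf_roi, frame_t, onsets_s) {
  rate <- 1 / median(diff(frame_t))
  w <- eventWindows(rate)
  k <- findInterval(onsets_s, frame_t)
  n <- length(zf_roi)
  k <- k[k - w$npre >= 1 & k + w$npost - 1 <= n]
  if (length(k) < 2) stop("need >= 2 events with complete windows")
  pre <- as.vector(vapply(k, function(i) zf_roi[(i - w$npre):(i - 1)],
                          numeric(w$npre)))
  post <- as.vector(vapply(k, function(i) zf_roi[i:(i + w$npost - 1)],
                           numeric(w$npost)))
  vp <- var(post); vq <- var(pre)
  den <- sqrt((vp + vq) / 2)
  if (den == 0) {
    d <- if (mean(post) == mean(pre)) 0 else sign(mean(post) - mean(pre)) * 100
    attr(d, "clipped") <- d != 0
    return(d)
  }
  (mean(post) - mean(pre)) / den
}

# Vectorized d-prime for a matrix of onset frames (shuffles x events).
# Same pooled formula as saccadeDprime, sample variances (n-1).
dprimeMatrix <- function(zf_roi, onsetFrames, npre, npost) {
  m <- nrow(onsetFrames); e <- ncol(onsetFrames)
  offs_pre <- -(npre:1); offs_post <- 0:(npost - 1)
  gather <- function(offs) {
    idx <- rep(onsetFrames, length(offs)) +
      rep(offs, each = m * e)                      # m x (e*length(offs))
    matrix(zf_roi[idx], nrow = m)
  }
  P <- gather(offs_post); Q <- gather(offs_pre)
  npn <- ncol(P); nqn <- ncol(Q)
  mp <- rowMeans(P); mq <- rowMeans(Q)
  vp <- (rowMeans(P * P) - mp^2) * npn / (npn - 1)
  vq <- (rowMeans(Q * Q) - mq^2) * nqn / (nqn - 1)
  den <- sqrt((vp + vq) / 2)
  d <- (mp - mq) / den
  d[den == 0] <- 0
  d
}

#' Permutation-null test for saccade-triggered activation
#'
#' Builds a null of \code{n_shuffle} d' values per saccade type by uniformly
#' redrawing the onset frames (event count preserved) and flags the ROI as
#' active for a type when the observed d' exceeds the null's 95th percentile.
#'
#' @param zf_roi one ROI's zF vector.
#' @param frame_t frame times (s).
#' @param onsets_by_type named list of onset-time vectors, one per type.
#' @param n_shuffle number of shuffles (default 1000).
#' @param seed RNG seed.
#' @return data.frame(type, dprime, null95, active).
#' @export
dprimeNullTest <- function(zf_roi, frame_t, onsets_by_type,
                           n_shuffle = 1000L, seed = 1L) {
  rate <- 1 / median(diff(frame_t))
  w <- eventWindows(rate)
  n <- length(zf_roi)
  lo <- w$npre + 1L; hi <- n - w$npost + 1L
  set.seed(childSeed(seed, 41L))
  res <- lapply(names(onsets_by_type), function(ty) {
    ons <- onsets_by_type[[ty]]
    d_obs <- saccadeDprime(zf_roi, frame_t, ons)
    k <- findInterval(ons, frame_t)
    k <- k[k - w$npre >= 1 & k + w$npost - 1 <= n]
    sh <- matrix(sample(lo:hi, n_shuffle * length(k), replace = TRUE),
                 nrow = n_shuffle)
    d_null <- dprimeMatrix(zf_roi, sh, w$npre, w$npost)
    q95 <- quantile(d_null, 0.95, names = FALSE)
    data.frame(type = ty, dprime = as.numeric(d_obs), null95 = q95,
               active = as.numeric(d_obs) > q95)
  })
  do.call(rbind, res)
}

#' Discretized calcium impulse response kernel
#'
#' h(t) = (1 - exp(-t/tauOn)) * exp(-t/tauOff) sampled at the frame rate on
#' t in [0, 5*tauOff], normalized to unit maximum.
#'
#' @param cirf a \linkS4class{CIRF}.
#' @param rate_hz frame rate.
#' @return numeric kernel vector.
#' @export
cirfKernel <- function(cirf, rate_hz) {
  t <- seq(0, 5 * cirf@tauOff, by = 1 / rate_hz)
  h <- (1 - exp(-t / cirf@tauOn)) * exp(-t / cirf@tauOff)
  h / max(h)
}

# Causal convolution with the CIRF kernel, then delay by `offset` frames.
convolveCIRF <- function(x, kernel, offset = 0L) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                       type = "open")[seq_len(n)]
  y[abs(y) < 1e-12] <- 0            # clear FFT round-off
  if (offset > 0) y <- c(numeric(offset), y[seq_len(n - offset)])
  y
}

spotAzBreaks <- seq(-60, 60, length.out = 5)

#' Build the 33-regressor design matrix
#'
#' Six oculomotor predictors: one-hot saccade onsets for ConvGL, ConvGR,
#' ConjL, ConjR, plus rectified nasal eye-position traces for each eye
#' (position minus the experiment-wide median, temporal side zeroed). Eight
#' locomotor predictors: swim onsets by direction x per-session vigour
#' quartile. Eighteen stimulus predictors: two grating-direction indicators
#' and 16 moving-spot one-hots (4 azimuth bins spanning -60..+60 deg x 2
#' directions x 2 contrast polarities). All 32 are convolved with the CIRF
#' and delayed by \code{offsetFrames}; the motion-error column is appended
#' unconvolved.
#'
#' @param events data.frame(onset_s, label) with labels ConvL/ConvR/ConjL/
#'   ConjR (ConvL maps to column sacc_ConvGL, etc.).
#' @param trace the session \linkS4class{EyeTrace}.
#' @param swims data.frame(time_s, direction, vigour).
#' @param stimuli list(gratings = data.frame(t_start, t_end, direction),
#'   spots = data.frame(t_start, t_end, direction, contrast, az_start),
#'   spot_speed_dps).
#' @param motion_error_um per-frame motion error.
#' @param frame_t frame times (s).
#' @param cirf a \linkS4class{CIRF}.
#' @param offsetFrames temporal offset in frames (0-3 in the search grid).
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesign <- function(events, trace, swims, stimuli, motion_error_um,
                        frame_t, cirf = CIRF(), offsetFrames = 0L) {
  if (is.null(events) || is.null(trace)) stop("missing predictor group: oculomotor")
  if (is.null(swims)) stop("missing predictor group: locomotor (swims)")
  if (is.null(stimuli) || is.null(stimuli$gratings) || is.null(stimuli$spots))
    stop("missing predictor group: stimulus")
  if (is.null(motion_error_um)) stop("missing predictor group: motion error")
  nf <- length(frame_t)
  rate <- 1 / median(diff(frame_t))
  onehot <- function(times) {
    v <- numeric(nf)
    k <- findInterval(times, frame_t - 0.5 / rate)
    k <- k[k >= 1 & k <= nf]
    v[k] <- 1
    v
  }
  X <- matrix(0, nf, 33L)
  cols <- character(33L)
  # --- oculomotor (6)
  map <- c(ConvL = "sacc_ConvGL", ConvR = "sacc_ConvGR",
           ConjL = "sacc_ConjL", ConjR = "sacc_ConjR")
  for (j in seq_along(map)) {
    cols[j] <- map[j]
    X[, j] <- onehot(events$onset_s[events$label == names(map)[j]])
  }
  # rectified nasal eye position (nasal-positive per eye; temporal side of
  # the experiment-wide median zeroed)
  nasal_l <- approx(trace@t, trace@left, xout = frame_t, rule = 2)$y
  nasal_r <- -approx(trace@t, trace@right, xout = frame_t, rule = 2)$y
  cols[5] <- "eyepos_nasal_L"; X[, 5] <- pmax(nasal_l - median(nasal_l), 0)
  cols[6] <- "eyepos_nasal_R"; X[, 6] <- pmax(nasal_r - median(nasal_r), 0)
  # --- locomotor (8): direction x vigour quartile, quartiles per session
  qs <- if (nrow(swims) > 0)
    ceiling(4 * rank(swims$vigour, ties.method = "first") / nrow(swims))
  else integer(0)
  j <- 6L
  for (dir in c("L", "R")) for (q in 1:4) {
    j <- j + 1L
    cols[j] <- sprintf("swim_%s_q%d", dir, q)
    X[, j] <- onehot(swims$time_s[swims$direction == dir & qs == q])
  }
  # --- stimulus (18): gratings (2) + spots (16)
  for (dir in c("L", "R")) {
    j <- j + 1L
    cols[j] <- sprintf("grat_%s", dir)
    g <- stimuli$gratings[stimuli$gratings$direction == dir, , drop = FALSE]
    v <- numeric(nf)
    for (i in seq_len(nrow(g)))
      v[frame_t >= g$t_start[i] & frame_t < g$t_end[i]] <- 1
    X[, j] <- v
  }
  speed <- if (!is.null(stimuli$spot_speed_dps)) stimuli$spot_speed_dps else 30
  sp <- stimuli$spots
  for (bin in 1:4) for (dir in c("L", "R")) for (con in c(1, -1)) {
    j <- j + 1L
    cols[j] <- sprintf("spot_az%d_%s_%s", bin, dir, if (con > 0) "b" else "d")
    v <- numeric(nf)
    rows <- which(sp$direction == dir & sp$contrast == con)
    for (i in rows) {
      az <- sp$az_start[i] +
        (if (dir == "R") 1 else -1) * speed * (frame_t - sp$t_start[i])
      inb <- frame_t >= sp$t_start[i] & frame_t < sp$t_end[i] &
        az >= spotAzBreaks[bin] & az < spotAzBreaks[bin + 1]
      v[inb] <- 1
    }
    X[, j] <- v
  }
  # convolve + offset all but the motion column
  kern <- cirfKernel(cirf, rate)
  for (c2 in seq_len(32L)) X[, c2] <- convolveCIRF(X[, c2], kern, offsetFrames)
  cols[33] <- "motion_error"
  X[, 33] <- motion_error_um
  colnames(X) <- cols
  groups <- factor(c(rep("oculomotor", 6), rep("locomotor", 8),
                     rep("stimulus", 18), "motion"),
                   levels = c("oculomotor", "locomotor", "stimulus", "motion"))
  new("DesignMatrix", X = X, groups = groups, cirf = cirf,
      offsetFrames = as.integer(offsetFrames))
}

#' Precompute the 12 designs of the hyperparameter grid
#'
#' @inheritParams buildDesign
#' @param tau_off_grid,offset_grid the search grids (3/4/5 s; 0-3 frames).
#' @return named list of \linkS4class{DesignMatrix} objects
#'   ("tau<T>_off<K>"), shared across ROIs.
#' @export
designGrid <- function(events, trace, swims, stimuli, motion_error_um, frame_t,
                       tau_off_grid = c(3, 4, 5), offset_grid = 0:3) {
  out <- list()
  for (tau in tau_off_grid) for (off in offset_grid)
    out[[sprintf("tau%g_off%d", tau, off)]] <-
      buildDesign(events, trace, swims, stimuli, motion_error_um, frame_t,
                  cirf = CIRF(0.2, tau), offsetFrames = off)
  out
}

#' OLS hyperparameter search
#'
#' Exhaustive search over the CIRF decay constant (3, 4, 5 s) and the
#' regressor frame offset (0-3): ordinary least squares of the ROI's zF on
#' each candidate design; returns the argmax-R^2 pair and whether the gate
#' R^2 > 0.05 is passed. A rank-deficient design falls back to a tiny-ridge
#' solve and is flagged.
#'
#' @param zf_roi one ROI's zF vector.
#' @param designs list from \code{\link{designGrid}}.
#' @param gate_r2 gate threshold (default 0.05).
#' @return list(best_tau_off, best_offset, ols_r2, gate, flagged).
#' @export
olsHyperparamSearch <- function(zf_roi, designs, gate_r2 = 0.05) {
  y <- zf_roi - mean(zf_roi)
  tss <- sum(y^2)
  best <- list(r2 = -Inf)
  flagged <- FALSE
  for (nm in names(designs)) {
    X <- designMatrix(designs[[nm]])
    Xc <- scale(X, center = TRUE, scale = FALSE)
    qrx <- qr(Xc)
    if (qrx$rank < ncol(Xc)) {
      flagged <- TRUE
      G <- crossprod(Xc) + diag(1e-8, ncol(Xc))
      beta <- solve(G, crossprod(Xc, y))
      res <- y - Xc %*% beta
    } else res <- qr.resid(qrx, y)
    r2 <- 1 - sum(res^2) / tss
    if (r2 > best$r2) {
      d <- designs[[nm]]
      best <- list(r2 = r2, tau = d@cirf@tauOff, off = d@offsetFrames)
    }
  }
  list(best_tau_off = best$tau, best_offset = best$off, ols_r2 = best$r2,
       gate = best$r2 > gate_r2, flagged = flagged)
}

#' Ridge regression with 10-fold cross-validation
#'
#' X is standardized (zero-variance columns become all-zero) and y centred;
#' no intercept is fitted. Folds are contiguous frame blocks, limiting
#' autocorrelation leakage between train and test. Lambda is chosen from a
#' 13-point log grid spanning 1e-3..1e3 by out-of-fold R^2; the returned
#' coefficients come from the full-data fit at the chosen lambda.
#'
#' @param zf_roi one ROI's zF vector.
#' @param X design matrix (frames x regressors).
#' @param lambda_grid penalty grid (on the standardized scale).
#' @param nfolds number of contiguous folds (default 10).
#' @return list(lambda, cvR2, coefficients, folds, center, scale, cv_path).
#' @export
ridgeCvFit <- function(zf_roi, X, lambda_grid = 10^seq(-3, 3, by = 0.5),
                       nfolds = 10L) {
  n <- nrow(X)
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  sc[sc == 0] <- Inf          # zero-variance column -> all zeros
  Xs <- sweep(sweep(X, 2, mu), 2, sc, "/")
  y <- zf_roi - mean(zf_roi)
  folds <- rep(seq_len(nfolds), each = ceiling(n / nfolds))[seq_len(n)]
  p <- ncol(Xs)
  sse <- numeric(length(lambda_grid))
  for (f in seq_len(nfolds)) {
    te <- folds == f
    sv <- svd(Xs[!te, , drop = FALSE])
    uty <- crossprod(sv$u, y[!te])
    for (li in seq_along(lambda_grid)) {
      w <- sv$d / (sv$d^2 + lambda_grid[li])
      beta <- sv$v %*% (w * uty)
      sse[li] <- sse[li] + sum((y[te] - Xs[te, , drop = FALSE] %*% beta)^2)
    }
  }
  tss <- sum(y^2)
  cv_path <- 1 - sse / tss
  li <- which.max(cv_path)
  lambda <- lambda_grid[li]
  beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, y))
  list(lambda = lambda, cvR2 = cv_path[li],
       coefficients = setNames(drop(beta), colnames(X)),
       folds = folds, center = mu, scale = sc, cv_path = cv_path)
}

# Out-of-fold R^2 at fixed lambda/folds, with per-fold Gram updates for a
# single permuted column (used by deltaCvR2; exact, just organized so the
# expensive crossprod is computed once per fold).
cvR2Fixed <- function(y, Xs, folds, lambda) {
  sse <- 0
  for (f in unique(folds)) {
    te <- folds == f
    Xtr <- Xs[!te, , drop = FALSE]
    beta <- solve(crossprod(Xtr) + diag(lambda, ncol(Xs)),
                  crossprod(Xtr, y[!te]))
    sse <- sse + sum((y[te] - Xs[te, , drop = FALSE] %*% beta)^2)
  }
  1 - sse / sum(y^2)
}

#' Unique-variance attribution by circular permutation
#'
#' For each regressor in turn, circularly shift its (standardized) column by
#' a seeded random offset of at least 10 frames, recompute the
#' cross-validated fit with the same lambda and folds, and report
#' delta cvR^2 = permuted cvR^2 - original cvR^2. Negative values mean the
#' regressor carried unique explanatory signal.
#'
#' @param zf_roi one ROI's zF vector.
#' @param X design matrix used for the original fit.
#' @param fit result of \code{\link{ridgeCvFit}}.
#' @param seed RNG seed (the drawn shifts are recorded in the output).
#' @return data.frame(regressor, shift, cvR2_perm, delta_cvR2).
#' @export
deltaCvR2 <- function(zf_roi, X, fit, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  y <- zf_roi - mean(zf_roi)
  folds <- fit$folds
  ufolds <- sort(unique(folds))
  # per-fold cached pieces
  cache <- lapply(ufolds, function(f) {
    te <- folds == f
    Xtr <- Xs[!te, , drop = FALSE]
    list(te = te, tr = !te, G = crossprod(Xtr), Xty = crossprod(Xtr, y[!te]))
  })
  set.seed(childSeed(seed, 51L))
  shifts <- sample(10:(n - 10), p, replace = TRUE)
  out <- data.frame(regressor = colnames(X), shift = shifts,
                    cvR2_perm = NA_real_, delta_cvR2 = NA_real_)
  tss <- sum(y^2)
  for (j in seq_len(p)) {
    xp <- Xs[c((shifts[j] + 1):n, 1:shifts[j]), j]
    sse <- 0
    for (cf in cache) {
      G <- cf$G; Xty <- cf$Xty
      xtr <- xp[cf$tr]
      v <- crossprod(Xs[cf$tr, , drop = FALSE], xtr)  # X' xp on train
      v[j] <- sum(xtr * xtr)
      G[j, ] <- v; G[, j] <- v
      Xty[j] <- sum(xtr * y[cf$tr])
      beta <- solve(G + diag(fit$lambda, p), Xty)
      pred <- Xs[cf$te, , drop = FALSE] %*% beta +
        (xp[cf$te] - Xs[cf$te, j]) * beta[j]
      sse <- sse + sum((y[cf$te] - pred)^2)
    }
    out$cvR2_perm[j] <- 1 - sse / tss
  }
  out$delta_cvR2 <- out$cvR2_perm - fit$cvR2
  out
}

#' Classify oculomotor-tuned ROIs
#'
#' Pools the positive delta-cvR^2 values across all gated ROIs and regressors
#' as the permutation null (usable two-sided by mirroring about zero) and
#' labels an ROI oculomotor-tuned when (i) its most negative delta cvR^2
#' belongs to an oculomotor regressor, (ii) at least one oculomotor regressor
#' is more negative than minus the null's 95th percentile, and (iii) the
#' motion-error regressor is less negative than that bound. Tuned ROIs get a
#' type label from their d' activation flags: "Both" when convergent plus at
#' least one conjugate type is active, otherwise the single active type
#' (largest d' on ties).
#'
#' @param delta_list named list (per ROI) of \code{\link{deltaCvR2}} outputs.
#' @param dprime_list named list (per ROI) of \code{\link{dprimeNullTest}}
#'   outputs; types must be "Conv", "LConj", "RConj".
#' @param groups factor of regressor groups (from the design).
#' @param min_null_pool minimum pooled positive values required.
#' @return data.frame(roi, tuned, label, most_negative, crit1, crit2, crit3)
#'   with the null 95th percentile in \code{attr(, "null95")}.
#' @export
classifyTuned <- function(delta_list, dprime_list, groups,
                          min_null_pool = 50L) {
  pos <- unlist(lapply(delta_list, function(d) d$delta_cvR2[d$delta_cvR2 > 0]))
  if (length(pos) < min_null_pool)
    stop("need >= ", min_null_pool, " pooled positive delta-cvR2 values for the null")
  q95 <- quantile(pos, 0.95, names = FALSE)
  ocu <- groups == "oculomotor"
  mot <- groups == "motion"
  rows <- lapply(names(delta_list), function(roi) {
    d <- delta_list[[roi]]$delta_cvR2
    crit1 <- ocu[which.min(d)]
    crit2 <- min(d[ocu]) < -q95
    crit3 <- d[mot] > -q95
    tuned <- crit1 && crit2 && crit3
    label <- "none"
    if (tuned) {
      dp <- dprime_list[[roi]]
      act <- dp$type[dp$active]
      if ("Conv" %in% act && any(c("LConj", "RConj") %in% act)) label <- "Both"
      else if (length(act) == 1) label <- act
      else if (length(act) > 1) label <- act[which.max(dp$dprime[dp$active])]
      else { tuned <- FALSE; label <- "none" }  # no d' flag: not saccade-active
    }
    data.frame(roi = roi, tuned = tuned, label = label,
               most_negative = delta_list[[roi]]$regressor[which.min(d)],
               crit1 = crit1, crit2 = crit2, crit3 = unname(crit3))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "null95") <- q95
  out
}

#' Run the full encoding stage for every ROI
#'
#' d' permutation test per saccade type (Conv pooled across lateralizations
#' for the activation test, LConj/RConj separate), OLS hyperparameter search
#' for saccade-active ROIs, ridge CV fit at the winning design, circular
#' permutation delta-cvR^2, then the three-criterion tuned classification.
#'
#' @param fset \linkS4class{FluorescenceSet} (zF computed if absent).
#' @param events labeled events data.frame(onset_s, label).
#' @param trace,swims,stimuli session logs (see \code{\link{buildDesign}}).
#' @param seed RNG seed for all permutation draws.
#' @param n_shuffle shuffles for the d' null.
#' @return list(dprime, search, fits, delta, tuned, designs).
#' @export
encodeSession <- function(fset, events, trace, swims, stimuli, seed = 1L,
                          n_shuffle = 1000L) {
  if (!("zF" %in% SummarizedExperiment::assayNames(fset)))
    fset <- computeZF(fset)
  Z <- zF(fset)
  frame_t <- frameTimes(fset)
  onsets <- list(
    Conv = events$onset_s[grepl("^Conv", events$label)],
    LConj = events$onset_s[events$label == "ConjL"],
    RConj = events$onset_s[events$label == "ConjR"])
  onsets <- onsets[vapply(onsets, length, 1L) >= 2]
  designs <- designGrid(events, trace, swims, stimuli, motionError(fset), frame_t)
  dprime <- list(); search <- list(); fits <- list(); delta <- list()
  for (r in seq_len(nrow(Z))) {
    roi <- rownames(Z)[r]
    dp <- dprimeNullTest(Z[r, ], frame_t, onsets, n_shuffle,
                         seed = childSeed(seed, 100L + r))
    dprime[[roi]] <- dp
    if (!any(dp$active)) next
    s <- olsHyperparamSearch(Z[r, ], designs)
    search[[roi]] <- s
    if (!s$gate) next
    X <- designMatrix(designs[[sprintf("tau%g_off%d", s$best_tau_off, s$best_offset)]])
    fit <- ridgeCvFit(Z[r, ], X)
    fits[[roi]] <- fit
    delta[[roi]] <- deltaCvR2(Z[r, ], X, fit, seed = childSeed(seed, 200L + r))
  }
  tuned <- if (length(delta))
    classifyTuned(delta, dprime, regressorGroups(designs[[1]])) else NULL
  list(dprime = dprime, search = search, fits = fits, delta = delta,
       tuned = tuned, designs = designs)
}
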