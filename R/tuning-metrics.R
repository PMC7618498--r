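# Per-ROI oculomotor tuning metrics: normalized saccade-triggered
# fluorescence, rectilinear eye-position fits, saccade-type index, OKR power,
# PC1 score and directionality preference.

#' Normalized saccade-triggered fluorescence
#'
#' Per saccade: subtract the mean zF over the 1 s window before onset, sum zF
#' over the 2 s window from onset, then divide all values by their 95th
#' percentile across saccades for the ROI. A non-positive 95th percentile
#' falls back to its absolute value and is flagged.
#'
#' @param zf_roi one ROI's zF vector.
#' @param frame_t frame times (s).
#' @param onsets_s saccade onset times (>= 5 required).
#' @return numeric vector, one value per saccade (NA where windows leave the
#'   recording); attribute \code{"flagged"} marks the degenerate-percentile
#'   fallback.
#' @export
normalizedStf <- function(zf_roi, frame_t, onsets_s) {
  if (length(onsets_s) < 5) stop("need >= 5 saccades")
  rate <- 1 / median(diff(frame_t))
  w <- eventWindows(rate)
  n <- length(zf_roi)
  k <- findInterval(onsets_s, frame_t)
  raw <- vapply(k, function(i) {
    if (i - w$npre < 1 || i + w$npost - 1 > n) return(NA_real_)
    b <- mean(zf_roi[(i - w$npre):(i - 1)])
    sum(zf_roi[i:(i + w$npost - 1)] - b)
  }, numeric(1))
  q <- quantile(raw, 0.95, na.rm = TRUE, names = FALSE)
  flagged <- FALSE
  if (!is.finite(q) || q <= 0) { q <- abs(q); flagged <- q > 0 }
  out <- if (q > 0) raw / q else raw
  attr(out, "flagged") <- flagged
  out
}

#' Rectilinear (baseline + ramp) tuning fit
#'
#' Fits fluorescence versus normalized post-saccadic eye position with a
#' horizontal baseline (median over the baseline span) plus a linear ramp
#' starting at a threshold position, over a grid of 41 candidate breakpoints
#' spanning the observed positions (the last candidate is the baseline-only
#' model). The minimum-MSE candidate is selected; the ramp is accepted only
#' if its fitted excursion exceeds \code{accept_k} times the RMSE of the
#' baseline-only fit, otherwise the baseline-only fit is returned.
#'
#' @param values normalized saccade-triggered fluorescence.
#' @param positions normalized post-saccadic eye positions (>= 10 pairs).
#' @param n_grid breakpoint candidates (default 41).
#' @param accept_k ramp acceptance multiple (default 2).
#' @return list(baseline, breakpoint, slope, mse, mse_baseline_only, r2,
#'   ramp_accepted, flagged).
#' @export
rectilinearFit <- function(values, positions, n_grid = 41L, accept_k = 2) {
  ok <- is.finite(values) & is.finite(positions)
  y <- values[ok]; x <- positions[ok]
  if (length(y) < 10) stop("need >= 10 (position, value) pairs")
  base_all <- median(y)
  mse0 <- mean((y - base_all)^2)
  if (diff(range(x)) < 1e-9)
    return(list(baseline = base_all, breakpoint = NA_real_, slope = NA_real_,
                mse = mse0, mse_baseline_only = mse0, r2 = 0,
                ramp_accepted = FALSE, flagged = TRUE))
  grid <- seq(min(x), max(x), length.out = n_grid)
  best <- list(mse = Inf)
  for (c0 in grid) {
    inb <- x <= c0
    if (!any(inb)) next
    b <- median(y[inb])
    ramp <- !inb
    if (any(ramp)) {
      dx <- x[ramp] - c0
      slope <- sum(dx * (y[ramp] - b)) / sum(dx * dx)
      fit <- ifelse(inb, b, b + slope * (x - c0))
    } else { slope <- NA_real_; fit <- rep(b, length(y)) }
    mse <- mean((y - fit)^2)
    if (mse < best$mse)
      best <- list(mse = mse, breakpoint = c0, slope = slope, baseline = b,
                   has_ramp = any(ramp))
  }
  excursion <- if (isTRUE(best$has_ramp))
    abs(best$slope) * (max(x) - best$breakpoint) else 0
  accepted <- isTRUE(best$has_ramp) && is.finite(excursion) &&
    excursion > accept_k * sqrt(mse0)
  if (!accepted)
    best <- list(mse = mse0, breakpoint = NA_real_, slope = NA_real_,
                 baseline = base_all, has_ramp = FALSE)
  vy <- var(y) * (length(y) - 1) / length(y)
  list(baseline = best$baseline, breakpoint = best$breakpoint,
       slope = best$slope, mse = best$mse, mse_baseline_only = mse0,
       r2 = if (vy > 0) 1 - best$mse / vy else 0,
       ramp_accepted = accepted, flagged = FALSE)
}

# Per-event nasal amplitude / nasal peak velocity for one eye in the shared
# rightward-positive frame (left eye nasal = +, right eye nasal = -).
nasalKinematics <- function(events, eye) {
  if (eye == "right")
    data.frame(pos = -events$med_post_r, vel = -events$vel_ccw_r,
               amp = -events$amp_r)
  else
    data.frame(pos = events$med_post_l, vel = events$vel_cw_l,
               amp = events$amp_l)
}

#' Saccade-type index
#'
#' For each conjugate adducting saccade of the assigned eye, the closest
#' convergent saccade within Euclidean distance 0.1 in normalized
#' (post-saccadic position, velocity) space is matched; the index is the
#' median difference in normalized saccade-triggered fluorescence across the
#' matched pairs (convergent minus conjugate; positive = stronger convergent
#' response). NA when no pairs match.
#'
#' @param stf normalized saccade-triggered fluorescence (one per event).
#' @param events detected/labeled events data.frame.
#' @param eye which eye's kinematics to use ("left"/"right").
#' @param radius matching radius (default 0.1).
#' @param replace if TRUE (default) a convergent saccade may partner several
#'   conjugates; FALSE removes each convergent partner once matched.
#' @return list(index, n_pairs, pairs).
#' @export
saccadeTypeIndex <- function(stf, events, eye, radius = 0.1, replace = TRUE) {
  kin <- nasalKinematics(events, eye)
  adduct_conj <- grepl("^Conj", events$label) & kin$amp > 0
  conv <- grepl("^Conv", events$label)
  pos_max <- max(kin$pos[conv | adduct_conj], na.rm = TRUE)
  vel_q <- quantile(kin$vel[kin$vel > 0], 0.95, na.rm = TRUE, names = FALSE)
  if (!is.finite(pos_max) || pos_max <= 0 || !is.finite(vel_q) || vel_q <= 0)
    return(list(index = NA_real_, n_pairs = 0L, pairs = NULL))
  np <- kin$pos / pos_max
  nv <- kin$vel / vel_q
  conv_i <- which(conv & is.finite(stf))
  conj_i <- which(adduct_conj & is.finite(stf))
  avail <- rep(TRUE, length(conv_i))
  pairs <- NULL
  for (ci in conj_i) {
    cand <- conv_i[avail | replace]
    if (!length(cand)) next
    d <- sqrt((np[cand] - np[ci])^2 + (nv[cand] - nv[ci])^2)
    j <- which.min(d)
    if (d[j] < radius) {
      pairs <- rbind(pairs, data.frame(conj = ci, conv = cand[j],
                                       diff = stf[cand[j]] - stf[ci]))
      if (!replace) avail[match(cand[j], conv_i)] <- FALSE
    }
  }
  if (is.null(pairs)) return(list(index = NA_real_, n_pairs = 0L, pairs = NULL))
  list(index = median(pairs$diff), n_pairs = nrow(pairs), pairs = pairs)
}

#' OKR power
#'
#' Median zF across leftward-grating presentations minus the median across
#' rightward presentations (epoch-aligned), mirrored into one full
#' direction-alternation cycle, Fourier transformed; the score is the power
#' spectral density at the bin nearest the alternation frequency
#' (1 / (2 * epoch duration)). Zero for direction-symmetric responses and
#' invariant to the DC offset of zF.
#'
#' @param zf_roi one ROI's zF vector.
#' @param frame_t frame times (s).
#' @param gratings data.frame(t_start, t_end, direction) with >= 3
#'   presentations per direction.
#' @return scalar power.
#' @export
okrPower <- function(zf_roi, frame_t, gratings) {
  if (is.null(gratings) || nrow(gratings) == 0)
    stop("grating epochs (and hence the alternation frequency) are unknown")
  rate <- 1 / median(diff(frame_t))
  period <- median(gratings$t_end - gratings$t_start)
  nf <- max(2L, floor(period * rate))
  segs <- function(dir) {
    g <- gratings[gratings$direction == dir, , drop = FALSE]
    k <- findInterval(g$t_start, frame_t) + 1L
    k <- k[k >= 1 & k + nf - 1 <= length(zf_roi)]
    if (length(k) < 3) stop("need >= 3 presentations per direction")
    t(vapply(k, function(i) zf_roi[i:(i + nf - 1)], numeric(nf)))
  }
  medL <- apply(segs("L"), 2, median)
  medR <- apply(segs("R"), 2, median)
  d <- medL - medR
  s <- c(d, -d)                        # one full alternation cycle
  N <- length(s)
  sp <- Mod(fft(s))^2 / N^2
  2 * sp[2]                            # bin at exactly 1/(2*period)
}

#' PC1 score
#'
#' Standardizes saccade-type index and OKR power across ROIs and projects on
#' the first principal component, sign-oriented so the saccade-type index
#' loads positively. Scores have zero mean by construction.
#'
#' @param index saccade-type indices (one per ROI, >= 10 non-NA).
#' @param power OKR power values (same length).
#' @return list(scores, loadings, var_explained).
#' @export
pc1Score <- function(index, power) {
  ok <- is.finite(index) & is.finite(power)
  if (sum(ok) < 10) stop("need >= 10 ROIs with both metrics")
  Z <- scale(cbind(index = index[ok], power = power[ok]))
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1]
  if (rot["index"] < 0) rot <- -rot
  scores <- rep(NA_real_, length(index))
  scores[ok] <- drop(Z %*% rot)
  list(scores = scores, loadings = rot,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Directionality preference from unique-variance values
#'
#' Sums delta-cvR^2 over the leftward-movement regressors (ConjL, ConvGL,
#' right-eye nasal position) and the rightward ones (ConjR, ConvGR, left-eye
#' nasal position); the more negative sum wins. A leftward preference routes
#' the saccade-type index and nasal ramp fits to the right eye (temporal fits
#' to the left eye), and vice versa. Exact ties default to leftward and are
#' flagged.
#'
#' @param delta a \code{\link{deltaCvR2}} data.frame for one ROI.
#' @return list(preference = "left"/"right", eye_for_nasal, tie).
#' @export
directionalityPreference <- function(delta) {
  d <- setNames(delta$delta_cvR2, delta$regressor)
  sl <- sum(d[c("sacc_ConjL", "sacc_ConvGL", "eyepos_nasal_R")])
  sr <- sum(d[c("sacc_ConjR", "sacc_ConvGR", "eyepos_nasal_L")])
  tie <- sl == sr
  pref <- if (sl <= sr) "left" else "right"
  list(preference = pref,
       eye_for_nasal = if (pref == "left") "right" else "left", tie = tie)
}

#' Compute all tuning metrics for the tuned ROIs of an encoding result
#'
#' @param fset \linkS4class{FluorescenceSet} with zF.
#' @param events labeled events.
#' @param enc result of \code{\link{encodeSession}}.
#' @param gratings grating epochs (for OKR power).
#' @return data.frame per ROI: directionality, saccade-type index, OKR power,
#'   PC1 score, rectilinear-fit summary for the preferred (nasal) eye.
#' @export
tuningMetrics <- function(fset, events, enc, gratings) {
  Z <- zF(fset); frame_t <- frameTimes(fset)
  rois <- names(enc$delta)
  rows <- lapply(rois, function(roi) {
    zf <- Z[roi, ]
    pref <- directionalityPreference(enc$delta[[roi]])
    stf <- normalizedStf(zf, frame_t, events$onset_s)
    sti <- saccadeTypeIndex(stf, events, pref$eye_for_nasal)
    kin <- nasalKinematics(events, pref$eye_for_nasal)
    pos_max <- max(kin$pos, na.rm = TRUE)
    rf <- tryCatch({
      sel <- kin$amp > 0 & is.finite(stf)
      rectilinearFit(stf[sel], kin$pos[sel] / pos_max)
    }, error = function(e) NULL)
    data.frame(roi = roi, preference = pref$preference,
               saccade_type_index = sti$index, n_pairs = sti$n_pairs,
               okr_power = okrPower(zf, frame_t, gratings),
               ramp_breakpoint = if (is.null(rf)) NA_real_ else rf$breakpoint,
               ramp_slope = if (is.null(rf)) NA_real_ else rf$slope,
               ramp_accepted = if (is.null(rf)) NA else rf$ramp_accepted)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && sum(is.finite(out$saccade_type_index) &
                           is.finite(out$okr_power)) >= 10) {
    pc <- pc1Score(out$saccade_type_index, out$okr_power)
    out$pc1_score <- pc$scores
  } else if (!is.null(out)) out$pc1_score <- NA_real_
  rownames(out) <- NULL
  out
}
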