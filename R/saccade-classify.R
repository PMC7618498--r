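# Saccade-type classification (supervised embedding + modal 100-NN vote),
# convergent-saccade lateralization, and velocity main-sequence fitting.

#' Classify saccades by modal 100-NN vote in the reference embedding
#'
#' Projects each normalized nine-metric vector into the reference space and
#' assigns the modal label of its 100 nearest reference neighbours
#' (Euclidean). Ties are broken by the summed inverse distance to the tied
#' labels' neighbours, which is deterministic given the input.
#'
#' @param metrics9_norm events x 9 matrix, normalized by
#'   \code{\link{normalizeMetrics}}. Rows with NA entries get label
#'   "unclassified".
#' @param ref a \linkS4class{ReferenceEmbedding} with >= 100 points.
#' @param k neighbourhood size of the modal vote (default 100).
#' @return character vector of labels.
#' @export
classifySaccades <- function(metrics9_norm, ref, k = 100L) {
  if (nrow(ref@coords) < k)
    stop("reference embedding must contain at least ", k, " points")
  M <- as.matrix(metrics9_norm)
  space <- if (ref@backend == "metric9") ref@model$space else ref@coords
  labs <- as.character(ref@labels)
  out <- character(nrow(M))
  for (i in seq_len(nrow(M))) {
    if (anyNA(M[i, ])) { out[i] <- "unclassified"; next }
    p <- if (ref@backend == "metric9") M[i, ]
         else drop((M[i, ] - ref@model$center) %*% ref@model$proj)
    d2 <- rowDist2(space, p)
    nn <- order(d2)[seq_len(k)]
    out[i] <- modalVote(labs[nn], sqrt(d2[nn]))
  }
  out
}

#' Lateralize convergent saccades by post-saccadic version
#'
#' Version is the average of the left- and right-eye median post-saccadic
#' positions (shared rightward-positive frame); positive version assigns
#' ConvR, negative ConvL. Exactly zero version falls back to a configurable
#' default and is flagged in \code{attr(, "tied")}.
#'
#' @param events event data.frame with \code{med_post_l}, \code{med_post_r}
#'   and \code{label} columns.
#' @param default label used when version is exactly zero.
#' @return the events data.frame with convergent labels replaced by
#'   ConvL/ConvR.
#' @export
lateralizeConvergent <- function(events, default = "ConvR") {
  conv <- grepl("^Conv", events$label)
  version <- (events$med_post_l + events$med_post_r) / 2
  tied <- conv & version == 0
  events$label[conv] <- ifelse(version[conv] > 0, "ConvR",
                               ifelse(version[conv] < 0, "ConvL", default))
  attr(events, "tied") <- which(tied)
  events
}

#' Fit the velocity main sequence
#'
#' Least-squares fit of the exponential saturation model
#' V = Vmax * (1 - exp(-A/A0)) to saccade amplitude (deg) and peak velocity
#' (deg/s), via Levenberg-Marquardt with a small grid restart when the first
#' attempt fails. AIC is the Gaussian form n*log(RSS/n) + 2k, k = 2.
#'
#' @param amplitudes positive amplitudes (deg); >= 10 saccades required.
#' @param velocities peak velocities (deg/s).
#' @return a \linkS4class{MainSequenceFit}; \code{converged = FALSE} flags a
#'   fit that needed the fallback grid or hit bounds.
#' @export
fitMainSequence <- function(amplitudes, velocities) {
  A <- as.numeric(amplitudes); V <- as.numeric(velocities)
  ok <- is.finite(A) & is.finite(V) & A > 0
  A <- A[ok]; V <- V[ok]
  n <- length(A)
  if (n < 10) stop("need at least 10 saccades to fit the main sequence")
  fit1 <- function(st) tryCatch(
    minpack.lm::nlsLM(V ~ Vmax * (1 - exp(-A / A0)), start = st,
                      lower = c(Vmax = 1, A0 = 0.05),
                      upper = c(Vmax = 1e5, A0 = 1e4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- fit1(list(Vmax = max(V), A0 = max(median(A) / 2, 0.5)))
  converged <- !is.null(fit)
  if (is.null(fit)) {
    grid <- expand.grid(Vmax = max(V) * c(0.8, 1.5, 3),
                        A0 = c(0.5, 2, 8, 32))
    for (i in seq_len(nrow(grid))) {
      fit <- fit1(as.list(grid[i, ]))
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) {            # flagged degenerate fit: report lm-free stats
    rss <- sum((V - mean(V))^2)
    return(new("MainSequenceFit", Vmax = max(mean(V), 1), A0 = max(median(A), 0.05),
               rss = rss, aic = gaussAIC(rss, n, 2), n = as.integer(n),
               converged = FALSE))
  }
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  new("MainSequenceFit", Vmax = unname(cf["Vmax"]), A0 = unname(cf["A0"]),
      rss = rss, aic = gaussAIC(rss, n, 2), n = as.integer(n),
      converged = converged)
}

#' Compare pooled versus type-specific main-sequence models
#'
#' Per eye: fit one pooled exponential (k = 2) to all saccades and separate
#' exponentials to the conjugate and convergent subsets (joint k = 4);
#' report the AIC difference (pooled - two-model; positive prefers the
#' two-model), the fraction of eyes preferring the two-model fit, the mean
#' two-model Akaike weight, and a signed-rank p value on the per-eye AIC
#' differences.
#'
#' @param data data.frame with columns \code{eye}, \code{type} ("Conj" or
#'   "Conv"), \code{amplitude}, \code{velocity}.
#' @param min_per_type eyes lacking this many saccades of either type are
#'   excluded (and counted in \code{n_excluded}).
#' @return list(per_eye, frac_two_model, mean_akaike_weight, p_signed_rank,
#'   n_eyes, n_excluded).
#' @export
compareMainSequenceModels <- function(data, min_per_type = 10) {
  eyes <- unique(data$eye)
  rows <- list(); excluded <- 0L
  for (e in eyes) {
    d <- data[data$eye == e, ]
    nConj <- sum(d$type == "Conj"); nConv <- sum(d$type == "Conv")
    if (nConj < min_per_type || nConv < min_per_type) {
      excluded <- excluded + 1L
      next
    }
    pooled <- fitMainSequence(d$amplitude, d$velocity)
    fConj <- fitMainSequence(d$amplitude[d$type == "Conj"], d$velocity[d$type == "Conj"])
    fConv <- fitMainSequence(d$amplitude[d$type == "Conv"], d$velocity[d$type == "Conv"])
    n <- nrow(d)
    rss2 <- fConj@rss + fConv@rss
    aic2 <- gaussAIC(rss2, n, 4)
    dAIC <- pooled@aic - aic2          # > 0: two-model preferred
    w2 <- 1 / (1 + exp(-dAIC / 2))     # Akaike weight of the two-model fit
    rows[[length(rows) + 1L]] <- data.frame(eye = e, aic_pooled = pooled@aic,
                                            aic_two = aic2, delta_aic = dAIC,
                                            akaike_weight_two = w2)
  }
  per_eye <- if (length(rows)) do.call(rbind, rows) else
    data.frame(eye = character(0), aic_pooled = numeric(0), aic_two = numeric(0),
               delta_aic = numeric(0), akaike_weight_two = numeric(0))
  p <- if (nrow(per_eye) >= 2)
    suppressWarnings(wilcox.test(per_eye$delta_aic, mu = 0)$p.value) else NA_real_
  list(per_eye = per_eye,
       frac_two_model = if (nrow(per_eye)) mean(per_eye$delta_aic > 0) else NA_real_,
       mean_akaike_weight = if (nrow(per_eye)) mean(per_eye$akaike_weight_two) else NA_real_,
       p_signed_rank = p, n_eyes = nrow(per_eye), n_excluded = excluded)
}
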