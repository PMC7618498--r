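# Saccade detection and per-event kinematics.
#
# Stage 1 (coarse): interpolate to 100 Hz, zero-phase low-pass at 1 Hz,
# convolve with a 160 ms antisymmetric step kernel and take supra-threshold
# peaks. Stage 2: pair left/right events within 100 ms, apply a 300 ms
# refractory discard. Stage 3 (refined): 500 Hz interpolation, guarded LOWESS
# smoothing, onset from the thresholded product of 100 ms and 40 ms step
# convolutions in a 400 ms window around the coarse peak. Stage 4: per-eye
# measures and the nine-metric event descriptor.

COARSE_RATE <- 100
FINE_RATE <- 500

#' Coarse per-eye saccade candidates
#'
#' @param trace an \linkS4class{EyeTrace} spanning at least 1 s.
#' @param threshold_deg detection threshold on the displacement-equivalent
#'   step convolution (default 1.5 deg).
#' @param all_peaks if TRUE return every local maximum of the convolution
#'   magnitude (no threshold); default keeps supra-threshold peaks only.
#' @return list with elements \code{left} and \code{right}: coarse peak times
#'   (s) per eye.
#' @export
detectCoarse <- function(trace, threshold_deg = 1.5, all_peaks = FALSE) {
  if (diff(range(trace@t)) < 1) stop("trace must span at least 1 s")
  bf <- signal::butter(2, 1 / (COARSE_RATE / 2), type = "low")
  # step response of the filter+convolution chain, so the threshold can be
  # stated in displacement degrees despite the 1 Hz low-pass attenuation
  ustep <- c(numeric(3 * COARSE_RATE), rep(1, 3 * COARSE_RATE))
  alpha <- max(abs(stepConv(as.numeric(signal::filtfilt(bf, ustep)),
                            0.160, COARSE_RATE)))
  oneEye <- function(x) {
    r <- resampleUniform(trace@t, x, COARSE_RATE)
    xf <- as.numeric(signal::filtfilt(bf, r$x))
    cv <- abs(stepConv(xf, 0.160, COARSE_RATE)) / alpha
    idx <- localMaxima(cv, if (all_peaks) 0 else threshold_deg)
    if (!all_peaks && length(idx)) {
      # constant-velocity slow phases (optokinetic tracking, divergence
      # drifts) pass the 1 Hz filter unattenuated and produce plateaus of
      # noise maxima in the convolution; require peaks to rise above the
      # shallower of their flanking minima by the detection threshold
      W <- as.integer(0.75 * COARSE_RATE)
      n <- length(cv)
      prom <- vapply(idx, function(i) {
        lo <- min(cv[max(1, i - W):i]); hi <- min(cv[i:min(n, i + W)])
        cv[i] - min(lo, hi)
      }, numeric(1))
      idx <- idx[prom >= threshold_deg]
    }
    # filter edge transients: candidates too close to the trace boundary
    # cannot be refined or measured anyway
    tt <- r$t[idx]
    tt[tt >= r$t[1] + 0.5 & tt <= r$t[length(r$t)] - 0.5]
  }
  list(left = oneEye(trace@left), right = oneEye(trace@right))
}

#' Pair per-eye events and apply the refractory discard
#'
#' Left- and right-eye candidates within 100 ms of one another are greedily
#' paired (nearest partner wins) into binocular events; unpaired candidates
#' stay monocular. Any event starting within 300 ms of the previous retained
#' event is then discarded (earliest event wins the conflict).
#'
#' @param eventsL,eventsR sorted coarse peak times (s) per eye.
#' @param pair_window_s,refractory_s pairing and refractory windows.
#' @return data.frame(time_l, time_r, time_s, binocular); NA for the absent
#'   eye of a monocular event.
#' @export
pairAndRefractory <- function(eventsL, eventsR, pair_window_s = 0.1,
                              refractory_s = 0.3) {
  usedR <- rep(FALSE, length(eventsR))
  rows <- list()
  for (tl in eventsL) {
    d <- abs(eventsR - tl)
    d[usedR] <- Inf
    j <- if (length(d)) which.min(d) else integer(0)
    if (length(j) && d[j] <= pair_window_s) {
      usedR[j] <- TRUE
      rows[[length(rows) + 1L]] <- c(tl, eventsR[j])
    } else rows[[length(rows) + 1L]] <- c(tl, NA_real_)
  }
  for (tr in eventsR[!usedR]) rows[[length(rows) + 1L]] <- c(NA_real_, tr)
  if (!length(rows))
    return(data.frame(time_l = numeric(0), time_r = numeric(0),
                      time_s = numeric(0), binocular = logical(0)))
  m <- do.call(rbind, rows)
  ev <- data.frame(time_l = m[, 1], time_r = m[, 2])
  ev$time_s <- pmin(ev$time_l, ev$time_r, na.rm = TRUE)
  ev$binocular <- !is.na(ev$time_l) & !is.na(ev$time_r)
  ev <- ev[order(ev$time_s), , drop = FALSE]
  keep <- logical(nrow(ev))
  last <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$time_s[i] - last > refractory_s) { keep[i] <- TRUE; last <- ev$time_s[i] }
  }
  rownames(ev) <- NULL
  ev[keep, , drop = FALSE]
}

# 500 Hz interpolation + guarded LOWESS smoothing of one eye over a local
# window. Samples where the 160 ms step convolution exceeds `guard_deg` are
# putative saccades and are left unsmoothed so the saccade profile (and its
# peak velocity) is preserved.
smoothFine <- function(trace, eye, t0, t1, span_s = 0.08, guard_deg = 3) {
  x <- eyePosition(trace, eye)
  r <- resampleUniform(trace@t, x, FINE_RATE, max(t0, trace@t[1]),
                       min(t1, trace@t[length(trace@t)]))
  n <- length(r$x)
  f <- min(1, span_s * FINE_RATE / n)
  sm <- stats::lowess(r$t, r$x, f = f, iter = 0)$y
  guard <- abs(stepConv(r$x, 0.160, FINE_RATE)) > guard_deg
  sm[guard] <- r$x[guard]
  list(t = r$t, x = sm)
}

#' Refine a saccade onset time
#'
#' Convolves the smoothed 500 Hz trace with 100 ms and 40 ms step kernels;
#' the onset is the first time within the 400 ms window centred on the coarse
#' peak where the product of the two convolutions crosses a threshold
#' (default 10% of the window maximum). Events whose product never exceeds
#' \code{abs_floor} (deg^2) carry no saccade and are rejected (NA).
#'
#' @param trace an \linkS4class{EyeTrace}.
#' @param coarse_peak_s coarse peak time (s); needs >= 200 ms margin in-trace.
#' @param eye "left" or "right".
#' @param rel_threshold onset threshold as a fraction of the window maximum.
#' @param abs_floor absolute floor on the window maximum (deg^2).
#' @return onset time (s) or NA if rejected.
#' @export
refineOnset <- function(trace, coarse_peak_s, eye, rel_threshold = 0.1,
                        abs_floor = 0.25) {
  t0 <- coarse_peak_s - 0.5; t1 <- coarse_peak_s + 0.5
  if (t0 < trace@t[1] - 1e-9 || t1 > trace@t[length(trace@t)] + 1e-9)
    return(NA_real_)
  f <- smoothFine(trace, eye, t0 - 0.2, t1 + 0.2)
  p <- stepConv(f$x, 0.100, FINE_RATE) * stepConv(f$x, 0.040, FINE_RATE)
  win <- f$t >= coarse_peak_s - 0.2 & f$t <= coarse_peak_s + 0.2
  if (!any(win)) return(NA_real_)
  pk <- max(p[win])
  if (pk < abs_floor) return(NA_real_)
  thr <- rel_threshold * pk
  iw <- which(win)
  cross <- iw[p[iw] >= thr]
  if (!length(cross)) return(NA_real_)
  f$t[cross[1]]
}

#' Per-eye saccade measures
#'
#' (a) pre-saccadic position: median over the 200 ms window before onset;
#' (b) max post-saccadic position: the position within 200 ms after onset
#' with greatest absolute deviation from the position at onset;
#' (c) median post-saccadic position: median over the 200 ms window starting
#' at the max-post time; (d) cw/ccw velocity: max and min of the central
#' time-derivative of the smoothed 500 Hz trace over a 150 ms window centred
#' at onset.
#'
#' @param trace an \linkS4class{EyeTrace}.
#' @param onset_s refined onset time (s).
#' @param eye "left" or "right".
#' @return named numeric vector (pre_pos, max_post, med_post, vel_cw,
#'   vel_ccw, t_max) or NULL when a window is truncated at the trace edge.
#' @export
computeMeasures <- function(trace, onset_s, eye) {
  lo <- onset_s - 0.25; hi <- onset_s + 0.65
  if (lo < trace@t[1] - 1e-9 || hi > trace@t[length(trace@t)] + 1e-9)
    return(NULL)
  f <- smoothFine(trace, eye, lo, hi)
  at <- function(a, b) f$x[f$t >= a & f$t < b]
  pre <- median(at(onset_s - 0.2, onset_s))
  post_i <- which(f$t >= onset_s & f$t < onset_s + 0.2)
  x_on <- f$x[which.min(abs(f$t - onset_s))]
  imax <- post_i[which.max(abs(f$x[post_i] - x_on))]
  t_max <- f$t[imax]
  max_post <- f$x[imax]
  med_post <- median(at(t_max, t_max + 0.2))
  vel_i <- which(f$t >= onset_s - 0.075 & f$t <= onset_s + 0.075)
  vel_i <- vel_i[vel_i > 1 & vel_i < length(f$x)]
  # central differences on the uniform 500 Hz grid
  g <- (f$x[vel_i + 1] - f$x[vel_i - 1]) * (FINE_RATE / 2)
  c(pre_pos = pre, max_post = max_post, med_post = med_post,
    vel_cw = max(g, na.rm = TRUE), vel_ccw = min(g, na.rm = TRUE),
    t_max = t_max)
}

metricNames <- c("amp_l", "amp_r", "maxmed_l", "maxmed_r",
                 "vel_cw_l", "vel_ccw_l", "vel_cw_r", "vel_ccw_r", "vergence")

#' Nine-metric event descriptor
#'
#' Amplitude (left, right) = median post - pre position; max-median amplitude
#' (left, right) = max post - median post; velocity (cw, ccw for each eye);
#' vergence = left - right median post-saccadic position (positive =
#' converged, given the shared rightward-positive frame). Monocular events
#' get NA in the missing eye's entries.
#'
#' @param mL,mR per-eye measure vectors from \code{\link{computeMeasures}}
#'   (either may be NULL for a monocular event).
#' @return numeric 9-vector in the fixed order \code{amp_l, amp_r, maxmed_l,
#'   maxmed_r, vel_cw_l, vel_ccw_l, vel_cw_r, vel_ccw_r, vergence}.
#' @export
nineMetrics <- function(mL, mR) {
  v <- setNames(rep(NA_real_, 9L), metricNames)
  if (!is.null(mL)) {
    v["amp_l"] <- mL["med_post"] - mL["pre_pos"]
    v["maxmed_l"] <- mL["max_post"] - mL["med_post"]
    v["vel_cw_l"] <- mL["vel_cw"]; v["vel_ccw_l"] <- mL["vel_ccw"]
  }
  if (!is.null(mR)) {
    v["amp_r"] <- mR["med_post"] - mR["pre_pos"]
    v["maxmed_r"] <- mR["max_post"] - mR["med_post"]
    v["vel_cw_r"] <- mR["vel_cw"]; v["vel_ccw_r"] <- mR["vel_ccw"]
  }
  if (!is.null(mL) && !is.null(mR))
    v["vergence"] <- mL["med_post"] - mR["med_post"]
  v
}

#' Winsorize and z-score metrics per animal
#'
#' Each metric column is clipped to its [0.5th, 99.5th] percentile range and
#' then z-scored with the mean and SD of the winsorized values, separately
#' per animal. Columns with zero variance after winsorizing are set to zero
#' and flagged in \code{attr(, "flat_columns")}.
#'
#' @param M numeric matrix (events x metrics).
#' @param animal optional grouping vector (one entry per event); default
#'   treats all events as one animal.
#' @return normalized matrix with the same dimensions.
#' @export
normalizeMetrics <- function(M, animal = NULL) {
  M <- as.matrix(M)
  if (is.null(animal)) animal <- rep(1L, nrow(M))
  if (min(table(animal)) < 2) stop("need >= 2 events per animal")
  out <- M
  flat <- character(0)
  for (g in unique(animal)) {
    rows <- animal == g
    for (j in seq_len(ncol(M))) {
      x <- M[rows, j]
      ok <- !is.na(x)
      q <- quantile(x[ok], c(0.005, 0.995), names = FALSE, type = 7)
      x[ok] <- pmin(pmax(x[ok], q[1]), q[2])
      s <- sd(x[ok])
      if (!is.finite(s) || s == 0) {
        x[ok] <- 0
        flat <- c(flat, paste0(g, ":", colnames(M)[j]))
      } else x[ok] <- (x[ok] - mean(x[ok])) / s
      out[rows, j] <- x
    }
  }
  attr(out, "flat_columns") <- flat
  out
}

#' Detect, refine and measure saccades in a binocular trace
#'
#' Runs the full kinematics stage: coarse detection per eye, binocular
#' pairing with the 300 ms refractory discard, per-eye onset refinement,
#' per-eye measures and the nine-metric descriptor. Events whose refinement
#' or measurement windows fail are dropped.
#'
#' @param trace an \linkS4class{EyeTrace}.
#' @param threshold_deg coarse detection threshold (deg).
#' @param all_peaks passed to \code{\link{detectCoarse}}.
#' @return data.frame with one row per retained event: onsets, coarse peak,
#'   binocular flag, per-eye measures and the nine metrics (columns
#'   \code{amp_l} ... \code{vergence}); \code{label} initialized to
#'   "unclassified".
#' @export
detectSaccades <- function(trace, threshold_deg = 1.5, all_peaks = FALSE) {
  cand <- detectCoarse(trace, threshold_deg, all_peaks)
  ev <- pairAndRefractory(cand$left, cand$right)
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    onL <- if (!is.na(ev$time_l[i])) refineOnset(trace, ev$time_l[i], "left") else NA_real_
    onR <- if (!is.na(ev$time_r[i])) refineOnset(trace, ev$time_r[i], "right") else NA_real_
    if (is.na(onL) && is.na(onR)) next
    mL <- if (!is.na(onL)) computeMeasures(trace, onL, "left") else NULL
    mR <- if (!is.na(onR)) computeMeasures(trace, onR, "right") else NULL
    if (is.null(mL) && is.null(mR)) next
    m9 <- nineMetrics(mL, mR)
    rows[[length(rows) + 1L]] <- data.frame(
      onset_l_s = onL, onset_r_s = onR,
      onset_s = min(onL, onR, na.rm = TRUE),
      coarse_peak_s = ev$time_s[i],
      binocular = !is.null(mL) && !is.null(mR),
      pre_pos_l = if (is.null(mL)) NA_real_ else mL[["pre_pos"]],
      pre_pos_r = if (is.null(mR)) NA_real_ else mR[["pre_pos"]],
      med_post_l = if (is.null(mL)) NA_real_ else mL[["med_post"]],
      med_post_r = if (is.null(mR)) NA_real_ else mR[["med_post"]],
      max_post_l = if (is.null(mL)) NA_real_ else mL[["max_post"]],
      max_post_r = if (is.null(mR)) NA_real_ else mR[["max_post"]],
      t(m9))
  }
  if (!length(rows)) {
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    out$label <- "unclassified"
    rownames(out) <- NULL
  }
  out
}
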