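# Synthetic session generator. Produces binocular eye traces, swim/stimulus
# logs and ROI fluorescence with recorded ground truth, so every downstream
# stage of the pipeline can be tested without any recorded data.

#' Session configuration for the synthetic generator
#'
#' Defaults describe a realistic tethered-larva imaging session: 4.8 Hz frame
#' scanning, eye tracking at 300 Hz, eye-tracking noise of 0.2 deg SD and
#' unit-SD calcium noise (zF is noise-normalized, so 1 is the natural scale).
#'
#' @param duration_s session length in seconds.
#' @param eye_rate_hz eye-tracking rate (60 or 300 Hz are typical).
#' @param imaging_rate_hz two-photon frame rate (Hz).
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @param eye_noise_sd_deg additive Gaussian noise on eye angles (deg).
#' @param calcium_noise_sd fluorescence noise SD in zF units.
#' @param n_rois_per_class ROIs generated per ground-truth class.
#' @param ms_params list with elements \code{Conj} and \code{Conv}, each
#'   c(Vmax, A0): the type-specific velocity main sequence (deg/s, deg).
#' @param cirf_tau_off,offset_frames the CIRF decay constant (s) and regressor
#'   frame offset used to generate fluorescence (the hyperparameters the
#'   encoding search should recover).
#' @param okr_slow_vel_dps optokinetic slow-phase velocity (deg/s).
#' @param okr_alt_period_s grating direction alternation period (s).
#' @param spot_speed_dps moving-spot azimuthal speed (deg/s).
#' @param conv_latency_s latency from spot trigger position to the evoked
#'   convergent saccade (configurable; no fidelity claim is attached).
#' @param swim_rate_hz rate of spontaneous swim bouts (1/s).
#' @return A list of class \code{"SessionConfig"}.
#' @export
sessionConfig <- function(duration_s = 600, eye_rate_hz = 300,
                          imaging_rate_hz = 4.8, rng_seed = 1L,
                          eye_noise_sd_deg = 0.2, calcium_noise_sd = 1,
                          n_rois_per_class = 8L,
                          ms_params = list(Conj = c(Vmax = 700, A0 = 6),
                                           Conv = c(Vmax = 1800, A0 = 25)),
                          cirf_tau_off = 4, offset_frames = 2L,
                          okr_slow_vel_dps = 6, okr_alt_period_s = 4,
                          spot_speed_dps = 30, conv_latency_s = 0.5,
                          swim_rate_hz = 0.08) {
  stopifnot(duration_s > 0, eye_rate_hz > 0, imaging_rate_hz > 0,
            eye_noise_sd_deg >= 0, calcium_noise_sd >= 0,
            n_rois_per_class >= 0)
  cfg <- list(duration_s = duration_s, eye_rate_hz = eye_rate_hz,
              imaging_rate_hz = imaging_rate_hz, rng_seed = as.integer(rng_seed),
              eye_noise_sd_deg = eye_noise_sd_deg,
              calcium_noise_sd = calcium_noise_sd,
              n_rois_per_class = as.integer(n_rois_per_class),
              ms_params = ms_params, cirf_tau_off = cirf_tau_off,
              offset_frames = as.integer(offset_frames),
              okr_slow_vel_dps = okr_slow_vel_dps,
              okr_alt_period_s = okr_alt_period_s,
              spot_speed_dps = spot_speed_dps, conv_latency_s = conv_latency_s,
              swim_rate_hz = swim_rate_hz)
  class(cfg) <- "SessionConfig"
  cfg
}

saccadeTypes <- c("ConvL", "ConvR", "ConjL", "ConjR")

# Peak velocity for one eye of one event, from the type-specific main sequence.
typePeakVel <- function(type, amp, ms_params) {
  p <- if (grepl("^Conv", type)) ms_params$Conv else ms_params$Conj
  mainSequenceVel(amp, p[["Vmax"]], p[["A0"]])
}

#' Build a saccade schedule
#'
#' Simple position-tracking schedule used for detection/classification tests:
#' conjugate saccades retarget gaze within +-8 deg of centre; convergent
#' saccades move both eyes nasally with a lateral bias that fixes the sign of
#' post-saccadic version, and are followed by a slow (non-saccadic) divergent
#' drift back to the pre-saccade positions.
#'
#' @param n number of saccades.
#' @param spacing_s mean inter-event spacing (>= 2 s keeps events clear of the
#'   300 ms refractory discard by construction).
#' @param types candidate types to draw from.
#' @param seed RNG seed.
#' @param amp_range conjugate amplitude range (deg).
#' @return A schedule list (saccades, drifts, slow, okr, spots, swims,
#'   duration_s) consumable by \code{\link{generateEyeTraces}}.
#' @export
makeSaccadeSchedule <- function(n, spacing_s = 2.5, types = saccadeTypes,
                                seed = 1L, amp_range = c(4, 14)) {
  stopifnot(spacing_s >= 2)
  set.seed(childSeed(seed, 11L))
  times <- 3 + cumsum(spacing_s * runif(n, 0.9, 1.1))
  type <- sample(types, n, replace = TRUE)
  amp_l <- amp_r <- numeric(n)
  a_min <- max(4, amp_range[1])
  drifts <- NULL
  pos <- 0  # conjugate gaze position (left == right between conv events)
  for (i in seq_len(n)) {
    if (grepl("^Conj", type[i])) {
      # retarget within +-8 deg; flip direction when the drawn one cannot
      # reach a detectable amplitude from the current position
      if (type[i] == "ConjR" && pos + a_min > 8) type[i] <- "ConjL"
      if (type[i] == "ConjL" && pos - a_min < -8) type[i] <- "ConjR"
      target <- if (type[i] == "ConjR") runif(1, pos + a_min, min(8, pos + amp_range[2]))
                else runif(1, max(-8, pos - amp_range[2]), pos - a_min)
      a <- target - pos
      amp_l[i] <- a * (1 + rnorm(1, 0, 0.04))
      amp_r[i] <- a * (1 + rnorm(1, 0, 0.04))
      pos <- pos + a
    } else {
      # convergent: left eye nasal (+), right eye nasal (-); version sign set
      # by the lateral bias of the two nasal amplitudes. Lateralization is
      # forced toward the feasible side when gaze sits far from centre.
      if (pos > 2) type[i] <- "ConvR"
      if (pos < -2) type[i] <- "ConvL"
      s <- if (type[i] == "ConvR") 1 else -1
      vpost <- s * runif(1, 1.5, 2.5) + pos / 2
      C <- runif(1, 13, 17)                 # total vergence change
      delta <- 2 * (vpost - pos)            # amp_l - amp_r (nasal magnitudes)
      delta <- max(min(delta, C - 7), -(C - 7))
      aL <- (C + delta) / 2; aR <- (C - delta) / 2
      amp_l[i] <- aL; amp_r[i] <- -aR
      drifts <- rbind(drifts, data.frame(t_start = times[i] + 1.2,
                                         t_end = times[i] + 4.2,
                                         d_l = -aL, d_r = aR))
      # hold fixation until the divergent drift completes
      if (i < n) times[(i + 1):n] <- times[(i + 1):n] + 2.5
    }
  }
  list(saccades = data.frame(time_s = times, type = type,
                             amp_l = amp_l, amp_r = amp_r),
       drifts = drifts, slow = NULL, okr = NULL, spots = NULL, swims = NULL,
       duration_s = max(times) + 5)
}

# Optokinetic block: alternating-direction slow phases plus conjugate reset
# saccades scheduled whenever the eye would leave +-8 deg. Returns epochs,
# slow-phase segments, reset saccades and the final gaze position.
okrBlock <- function(t0, n_epochs, period, vel, pos0, first_dir = 1) {
  epochs <- data.frame(t_start = t0 + (seq_len(n_epochs) - 1) * period,
                       t_end = t0 + seq_len(n_epochs) * period,
                       direction = rep_len(c(first_dir, -first_dir), n_epochs))
  slow <- data.frame(t_start = epochs$t_start, t_end = epochs$t_end,
                     v = vel * epochs$direction)
  resets <- NULL
  pos <- pos0
  for (k in seq_len(n_epochs)) {
    v <- slow$v[k]; t <- slow$t_start[k]
    while (TRUE) {
      hit <- max(0.1, if (v > 0) (8 - pos) / v else (-8 - pos) / v)
      t_hit <- t + hit
      if (t_hit >= slow$t_end[k] - 0.05) { pos <- pos + v * (slow$t_end[k] - t); break }
      a <- -sign(v) * 12            # reset to -sign(v) * 4
      resets <- rbind(resets, data.frame(time_s = t_hit,
                                         type = if (a > 0) "ConjR" else "ConjL",
                                         amp_l = a, amp_r = a))
      pos <- pos + v * hit + a
      t <- t_hit
    }
  }
  list(epochs = epochs, slow = slow, resets = resets, pos = pos)
}

#' Build a full session schedule
#'
#' Tiles the session with 60 s blocks, each containing an optokinetic grating
#' block (alternating direction, with reset saccades), three moving-spot trials
#' that evoke convergent saccades lateralized toward the spot, spontaneous
#' conjugate saccades, and Poisson swim bouts (40% of saccades also carry a
#' coincident swim, as tethered fish often swim when they saccade).
#'
#' @param cfg a \code{\link{sessionConfig}}.
#' @return A schedule list consumable by \code{\link{generateEyeTraces}}.
#' @export
makeSessionSchedule <- function(cfg) {
  set.seed(childSeed(cfg$rng_seed, 21L))
  n_blocks <- max(1L, floor(cfg$duration_s / 60))
  sacc <- NULL; drifts <- NULL; slow <- NULL; okr <- NULL; spots <- NULL
  pos <- 0
  for (b in seq_len(n_blocks)) {
    t0 <- (b - 1) * 60
    blk <- okrBlock(t0 + 2, n_epochs = 5, period = cfg$okr_alt_period_s,
                    vel = cfg$okr_slow_vel_dps, pos0 = pos,
                    first_dir = if (b %% 2 == 1) 1 else -1)
    okr <- rbind(okr, blk$epochs); slow <- rbind(slow, blk$slow)
    sacc <- rbind(sacc, blk$resets)
    pos <- blk$pos
    # recentering spontaneous conjugate saccade after the grating block
    a <- runif(1, -2, 2) - pos
    if (abs(a) < 4) a <- 4 * sign(a + 1e-9)
    sacc <- rbind(sacc, data.frame(time_s = t0 + 23.5 + runif(1, 0, 1),
                                   type = if (a > 0) "ConjR" else "ConjL",
                                   amp_l = a * (1 + rnorm(1, 0, 0.04)),
                                   amp_r = a * (1 + rnorm(1, 0, 0.04))))
    pos <- pos + a
    # three moving-spot trials, alternating direction, contrast alternating
    for (j in 1:3) {
      ts <- t0 + c(26, 37, 48)[j]
      dir <- c("R", "L", "R")[j]
      az0 <- if (dir == "R") -76 else 76
      spots <- rbind(spots, data.frame(
        t_start = ts, t_end = ts + 152 / cfg$spot_speed_dps, direction = dir,
        contrast = if ((b + j) %% 2 == 0) 1 else -1, az_start = az0))
      az_trig <- runif(1, -20, 20)
      t_conv <- ts + abs(az_trig - az0) / cfg$spot_speed_dps + cfg$conv_latency_s
      s <- if (az_trig >= 0) 1 else -1
      vpost <- s * runif(1, 1.5, 2.5)
      C <- runif(1, 13, 17)
      delta <- max(min(2 * (vpost - pos), C - 7), -(C - 7))
      aL <- (C + delta) / 2; aR <- (C - delta) / 2
      sacc <- rbind(sacc, data.frame(time_s = t_conv,
                                     type = if (s > 0) "ConvR" else "ConvL",
                                     amp_l = aL, amp_r = -aR))
      drifts <- rbind(drifts, data.frame(t_start = t_conv + 1.2,
                                         t_end = t_conv + 4.2,
                                         d_l = -aL, d_r = aR))
    }
    # one extra spontaneous conjugate saccade late in the block (wide scan)
    a <- runif(1, -8, 8) - pos
    if (abs(a) < 4) a <- 4 * sign(a + 1e-9)
    sacc <- rbind(sacc, data.frame(time_s = t0 + 57 + runif(1, 0, 1.5),
                                   type = if (a > 0) "ConjR" else "ConjL",
                                   amp_l = a * (1 + rnorm(1, 0, 0.04)),
                                   amp_r = a * (1 + rnorm(1, 0, 0.04))))
    pos <- pos + a
  }
  sacc <- sacc[order(sacc$time_s), ]
  rownames(sacc) <- NULL
  # swim bouts: Poisson background plus saccade-coupled bouts
  dur <- n_blocks * 60
  n_sw <- rpois(1, cfg$swim_rate_hz * dur)
  sw_t <- sort(runif(n_sw, 5, dur - 5))
  coup <- sacc$time_s[runif(nrow(sacc)) < 0.4]
  coup <- coup + runif(length(coup), 0, 0.1)
  swims <- data.frame(time_s = sort(c(sw_t, coup)))
  swims$direction <- sample(c("L", "R"), nrow(swims), replace = TRUE)
  swims$vigour <- rlnorm(nrow(swims), 0, 0.5)
  list(saccades = sacc, drifts = drifts, slow = slow, okr = okr,
       spots = spots, swims = swims, duration_s = dur)
}

#' Generate binocular eye traces from a schedule
#'
#' Saccades are minimum-jerk position steps whose analytic peak velocity
#' equals the type-specific main-sequence value Vmax*(1 - exp(-A/A0)) for the
#' per-eye amplitude; optokinetic epochs add constant-velocity slow phases;
#' post-convergence divergent drifts are smooth cosine ramps. Gaussian noise
#' of \code{cfg$eye_noise_sd_deg} is added to both eyes.
#'
#' @param cfg a \code{\link{sessionConfig}}.
#' @param schedule a schedule from \code{\link{makeSaccadeSchedule}} or
#'   \code{\link{makeSessionSchedule}}.
#' @return list(trace = \linkS4class{EyeTrace}, truth = ground-truth list).
#' @export
generateEyeTraces <- function(cfg, schedule) {
  dur <- if (!is.null(schedule$duration_s)) schedule$duration_s else cfg$duration_s
  t <- seq(0, dur, by = 1 / cfg$eye_rate_hz)
  n <- length(t)
  pos_l <- pos_r <- numeric(n)
  addStep <- function(pos, t0, D, amp, shape) {
    i0 <- findInterval(t0, t) + 1L
    i1 <- min(findInterval(t0 + D, t) + 1L, n)
    if (i0 <= i1) pos[i0:i1] <- pos[i0:i1] + amp * shape((t[i0:i1] - t0) / D)
    if (i1 < n) pos[(i1 + 1):n] <- pos[(i1 + 1):n] + amp
    pos
  }
  sc <- schedule$saccades
  pv_l <- pv_r <- dur_l <- dur_r <- numeric(nrow(sc))
  set.seed(childSeed(cfg$rng_seed, 5L))
  msj <- runif(nrow(sc), 0.88, 1.12)    # biological main-sequence dispersion
  for (i in seq_len(nrow(sc))) {
    pv_l[i] <- msj[i] * typePeakVel(sc$type[i], sc$amp_l[i], cfg$ms_params)
    pv_r[i] <- msj[i] * typePeakVel(sc$type[i], sc$amp_r[i], cfg$ms_params)
    dur_l[i] <- minJerkDuration(sc$amp_l[i], pv_l[i])
    dur_r[i] <- minJerkDuration(sc$amp_r[i], pv_r[i])
    pos_l <- addStep(pos_l, sc$time_s[i], dur_l[i], sc$amp_l[i], minJerk)
    pos_r <- addStep(pos_r, sc$time_s[i], dur_r[i], sc$amp_r[i], minJerk)
  }
  cosRamp <- function(tau) (1 - cos(pi * pmin(pmax(tau, 0), 1))) / 2
  for (d in seq_len(NROW(schedule$drifts))) {
    dr <- schedule$drifts[d, ]
    D <- dr$t_end - dr$t_start
    pos_l <- addStep(pos_l, dr$t_start, D, dr$d_l, cosRamp)
    pos_r <- addStep(pos_r, dr$t_start, D, dr$d_r, cosRamp)
  }
  for (s in seq_len(NROW(schedule$slow))) {
    sl <- schedule$slow[s, ]
    i0 <- findInterval(sl$t_start, t) + 1L
    i1 <- min(findInterval(sl$t_end, t) + 1L, n)
    if (i0 <= i1) {
      disp <- sl$v * (t[i0:i1] - sl$t_start)
      pos_l[i0:i1] <- pos_l[i0:i1] + disp
      pos_r[i0:i1] <- pos_r[i0:i1] + disp
      if (i1 < n) {
        tot <- sl$v * (sl$t_end - sl$t_start)
        pos_l[(i1 + 1):n] <- pos_l[(i1 + 1):n] + tot
        pos_r[(i1 + 1):n] <- pos_r[(i1 + 1):n] + tot
      }
    }
  }
  if (max(abs(c(pos_l, pos_r))) > 35)
    stop("schedule drives the eye beyond the +-35 deg orbital range")
  set.seed(childSeed(cfg$rng_seed, 1L))
  if (cfg$eye_noise_sd_deg > 0) {
    pos_l <- pos_l + rnorm(n, 0, cfg$eye_noise_sd_deg)
    pos_r <- pos_r + rnorm(n, 0, cfg$eye_noise_sd_deg)
  }
  truth <- list(
    saccades = data.frame(time_s = sc$time_s, type = sc$type,
                          amp_l = sc$amp_l, amp_r = sc$amp_r,
                          peak_vel_l = pv_l, peak_vel_r = pv_r),
    ms_params = cfg$ms_params)
  list(trace = EyeTrace(t, pos_l, pos_r), truth = truth)
}

#' Per-frame motion-error trace
#'
#' Sub-threshold baseline wander (0-2 um, lightly smoothed), Poisson-timed
#' excursions of 6-10 um (exercising the > 5 um interpolation rule) and
#' smaller 2.5-4.5 um bumps coupled to a subset of saccades, so that
#' motion-artifact ROIs correlate with saccades the way real residual motion
#' does.
#'
#' @param cfg a \code{\link{sessionConfig}}.
#' @param frame_t frame times (s).
#' @param saccade_times_s saccade onset times (s); 30% receive a bump.
#' @return numeric vector of motion error per frame (um).
#' @export
generateMotionError <- function(cfg, frame_t, saccade_times_s = numeric(0)) {
  set.seed(childSeed(cfg$rng_seed, 2L))
  n <- length(frame_t)
  base <- as.numeric(stats::filter(runif(n + 2, 0, 2), rep(1 / 3, 3),
                                   sides = 2))[2:(n + 1)]
  me <- base
  n_exc <- rpois(1, n / (40 * cfg$imaging_rate_hz))   # ~1 per 40 s
  if (n_exc > 0) {
    at <- sample(seq_len(n), n_exc)
    me[at] <- runif(n_exc, 6, 10)
  }
  if (length(saccade_times_s)) {
    hit <- saccade_times_s[runif(length(saccade_times_s)) < 0.3]
    fr <- findInterval(hit, frame_t)
    fr <- fr[fr >= 1 & fr < n]
    me[fr] <- me[fr] + runif(length(fr), 2.5, 4.5)
    me[fr + 1] <- me[fr + 1] + runif(length(fr), 1, 2.5)
  }
  pmax(me, 0)
}

# Ground-truth weight templates per ROI class, on design-matrix columns.
roiClasses <- c("mrmn_both", "mrmn_conv", "inn_like", "lrmn_like",
                "locomotor", "motion_artifact", "silent")

classWeightTemplate <- function(class, cols) {
  w <- setNames(numeric(length(cols)), cols)
  pick <- function(nm, val) { w[nm] <<- val }
  switch(class,
    mrmn_both = { pick("sacc_ConvGL", 2.5); pick("sacc_ConvGR", 2.5)
                  pick("sacc_ConjL", 2.5); pick("eyepos_nasal_R", 0.5) },
    mrmn_conv = { pick("sacc_ConvGL", 2.5); pick("sacc_ConvGR", 2.5) },
    inn_like  = { pick("sacc_ConjL", 2.5); pick("eyepos_nasal_R", 1.0) },
    lrmn_like = { pick("sacc_ConjR", 2.5); pick("eyepos_nasal_L", 1.0) },
    locomotor = { pick("swim_L_q3", 2.0); pick("swim_L_q4", 2.5)
                  pick("swim_R_q4", 2.0) },
    motion_artifact = { pick("motion_error", 0.6) },
    silent = { })
  w
}

#' Ground-truth ROI weights
#'
#' @param cfg a \code{\link{sessionConfig}}.
#' @param cols design-matrix column names.
#' @param classes ROI classes to generate (\code{n_rois_per_class} each).
#' @return list(W = ROI x regressor weight matrix, class = character vector).
#' @export
makeRoiWeights <- function(cfg, cols, classes = roiClasses) {
  set.seed(childSeed(cfg$rng_seed, 3L))
  cls <- rep(classes, each = cfg$n_rois_per_class)
  W <- t(vapply(cls, classWeightTemplate, numeric(length(cols)), cols = cols))
  W <- W * matrix(runif(length(W), 0.8, 1.25), nrow(W))  # per-ROI gain jitter
  rownames(W) <- sprintf("roi%03d", seq_along(cls))
  list(W = W, class = cls)
}

#' Generate ROI fluorescence from a design matrix and ground-truth weights
#'
#' F(roi, frame) = baseline + gain * (W X' + noise): the inverse of the
#' encoding model the analysis fits. Weights act on the CIRF-convolved
#' regressors (motion-artifact ROIs load on the unconvolved motion column).
#'
#' @param cfg a \code{\link{sessionConfig}}.
#' @param design a \linkS4class{DesignMatrix} built from the same session.
#' @param weights output of \code{\link{makeRoiWeights}} (or any list with
#'   \code{W} matching the design columns and \code{class}).
#' @param frame_t frame times; \code{motion_error_um} the per-frame motion
#'   trace (stored in the returned object).
#' @param baseline,gain raw-fluorescence offset and scale (arbitrary units;
#'   zF is invariant to them).
#' @return A \linkS4class{FluorescenceSet} with rowData columns
#'   \code{class} and the true weights.
#' @export
generateCalcium <- function(cfg, design, weights, frame_t, motion_error_um,
                            baseline = 100, gain = 10) {
  X <- designMatrix(design)
  if (ncol(X) != ncol(weights$W))
    stop("weight matrix does not match design columns")
  set.seed(childSeed(cfg$rng_seed, 4L))
  # columns normalized to unit peak so a weight is the ROI's peak response
  # amplitude (zF units) to that predictor, whatever the predictor's scale
  Xn <- sweep(X, 2, pmax(apply(abs(X), 2, max), 1e-12), "/")
  sig <- weights$W %*% t(Xn)
  noise <- matrix(rnorm(length(sig), 0, cfg$calcium_noise_sd), nrow(sig))
  F <- baseline + gain * (sig + noise)
  rownames(F) <- rownames(weights$W)
  FluorescenceSet(F, frame_t, motion_error_um,
                  rowData = data.frame(class = weights$class,
                                       row.names = rownames(F)))
}

#' Simulate a complete session with ground truth
#'
#' Runs the schedule builder, eye-trace generator, motion-error generator,
#' design construction (at the generator's true CIRF and offset) and
#' fluorescence generator, returning everything the analysis pipeline reads
#' plus the ground truth it should recover.
#'
#' @param cfg a \code{\link{sessionConfig}}.
#' @return list(trace, events, swims, stimuli, fluor, design, truth).
#' @export
simulateSession <- function(cfg = sessionConfig()) {
  schedule <- makeSessionSchedule(cfg)
  et <- generateEyeTraces(cfg, schedule)
  dt <- 1 / cfg$imaging_rate_hz
  frame_t <- seq(dt / 2, schedule$duration_s, by = dt)
  motion <- generateMotionError(cfg, frame_t, schedule$saccades$time_s)
  events <- data.frame(onset_s = schedule$saccades$time_s,
                       label = schedule$saccades$type)
  gratings <- data.frame(t_start = schedule$okr$t_start,
                         t_end = schedule$okr$t_end,
                         direction = ifelse(schedule$okr$direction > 0, "R", "L"))
  stimuli <- list(gratings = gratings, spots = schedule$spots,
                  spot_speed_dps = cfg$spot_speed_dps)
  design <- buildDesign(events, et$trace, schedule$swims, stimuli, motion,
                        frame_t, cirf = CIRF(0.2, cfg$cirf_tau_off),
                        offsetFrames = cfg$offset_frames)
  weights <- makeRoiWeights(cfg, regressorNames(design))
  fluor <- generateCalcium(cfg, design, weights, frame_t, motion)
  truth <- c(et$truth, list(roi_weights = weights$W, roi_class = weights$class,
                            cirf_tau_off = cfg$cirf_tau_off,
                            offset_frames = cfg$offset_frames))
  list(trace = et$trace, events = events, swims = schedule$swims,
       stimuli = stimuli, fluor = fluor, design = design, truth = truth,
       config = cfg)
}

# Draw synthetic nine-metric vectors for one saccade type directly from the
# kinematic model (amplitude geometry + type main sequence + measurement
# noise). Used to build the labeled reference set for the supervised
# embedding.
synthSaccadeMetrics <- function(type, n, ms_params,
                                vel_noise = 30, pos_noise = 0.3) {
  amp_l <- amp_r <- numeric(n)
  if (type %in% c("ConjL", "ConjR")) {
    A <- runif(n, 2, 18) * (if (type == "ConjR") 1 else -1)
    amp_l <- A * (1 + rnorm(n, 0, 0.05))
    amp_r <- A * (1 + rnorm(n, 0, 0.05))
    pre_l <- pre_r <- runif(n, -4, 4)
  } else {
    A <- runif(n, 6, 13)
    r <- runif(n, 0.35, 0.6)
    if (type == "ConvR") { amp_l <- A; amp_r <- -A * r }
    else { amp_l <- A * r; amp_r <- -A }
    pre_l <- pre_r <- runif(n, -2, 2)
  }
  velFor <- function(amp) {
    pv <- typePeakVel(type, abs(amp), ms_params) * (1 + rnorm(n, 0, 0.05))
    cw <- ifelse(amp > 0, pv, abs(rnorm(n, 0, vel_noise)))
    ccw <- ifelse(amp > 0, -abs(rnorm(n, 0, vel_noise)), -pv)
    cbind(cw, ccw)
  }
  vl <- velFor(amp_l); vr <- velFor(amp_r)
  maxmed_l <- rnorm(n, 0, pos_noise); maxmed_r <- rnorm(n, 0, pos_noise)
  verg <- (pre_l + amp_l) - (pre_r + amp_r) + rnorm(n, 0, pos_noise)
  m <- cbind(amp_l = amp_l + rnorm(n, 0, pos_noise),
             amp_r = amp_r + rnorm(n, 0, pos_noise),
             maxmed_l = maxmed_l, maxmed_r = maxmed_r,
             vel_cw_l = vl[, 1], vel_ccw_l = vl[, 2],
             vel_cw_r = vr[, 1], vel_ccw_r = vr[, 2],
             vergence = verg)
  m
}

#' Build a labeled reference embedding from synthetic saccade metrics
#'
#' Draws \code{n_per_type} nine-metric vectors per saccade type from the
#' kinematic model, normalizes them (winsorize + z-score) and fits a
#' supervised two-dimensional embedding (linear discriminant basis). New
#' events are classified by the modal label of their 100 nearest neighbours
#' in this space (\code{\link{classifySaccades}}).
#'
#' @param n_per_type labeled points per type (>= 200 recommended; < 100 is an
#'   error because the modal 100-NN vote is undefined).
#' @param seed RNG seed.
#' @param ms_params type main-sequence parameters (as in
#'   \code{\link{sessionConfig}}).
#' @param backend "lda2d" for the 2-D discriminant embedding, "metric9" for
#'   nearest-neighbour voting directly in the 9-D normalized space.
#' @return A \linkS4class{ReferenceEmbedding}.
#' @export
generateReferenceEmbedding <- function(n_per_type = 300, seed = 1L,
                                       ms_params = sessionConfig()$ms_params,
                                       backend = c("lda2d", "metric9")) {
  backend <- match.arg(backend)
  if (n_per_type < 100)
    stop("n_per_type must be >= 100: the modal 100-NN vote is undefined below that")
  set.seed(childSeed(seed, 31L))
  M <- do.call(rbind, lapply(saccadeTypes, synthSaccadeMetrics,
                             n = n_per_type, ms_params = ms_params))
  labels <- factor(rep(saccadeTypes, each = n_per_type), levels = saccadeTypes)
  if (length(unique(labels)) < 2)
    stop("reference set must contain at least two saccade types")
  Mn <- normalizeMetrics(M)
  fitReferenceEmbedding(Mn, labels, backend)
}

# Fit the supervised projection on an already-normalized labeled metric set.
fitReferenceEmbedding <- function(Mn, labels, backend = "lda2d") {
  labels <- droplevels(factor(labels))
  if (length(unique(labels)) < 2)
    stop("reference set must contain at least two saccade types")
  mu <- colMeans(Mn)
  if (backend == "lda2d") {
    ld <- MASS::lda(Mn, grouping = labels)
    proj <- ld$scaling[, seq_len(min(2, ncol(ld$scaling))), drop = FALSE]
    if (ncol(proj) == 1) proj <- cbind(proj, 0)
    coords <- sweep(Mn, 2, mu) %*% proj
  } else {
    pc <- prcomp(Mn, center = TRUE, scale. = FALSE)
    proj <- pc$rotation[, 1:2]
    coords <- sweep(Mn, 2, mu) %*% proj
  }
  colnames(coords) <- c("dim1", "dim2")
  new("ReferenceEmbedding", coords = coords, labels = labels,
      model = list(center = mu, proj = proj, space = if (backend == "metric9") Mn else NULL),
      backend = backend)
}
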