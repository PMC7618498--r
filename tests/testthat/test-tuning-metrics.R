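# Per-ROI tuning metrics: saccade-triggered fluorescence, rectilinear fits,
# saccade-type index, OKR power, PC1 score, directionality.

test_that("normalized saccade-triggered fluorescence follows its definition", {
  ft <- seq(0.1, 300, by = 1 / 4.8)
  onsets <- seq(20, 280, by = 20)   # spaced beyond the kernel support
  # flat zF -> all zero
  s0 <- normalizedStf(rep(2, length(ft)), ft, onsets)
  expect_true(all(s0[is.finite(s0)] == 0))
  # identical responses to every saccade -> all normalized values equal 1
  kern <- cirfKernel(CIRF(0.2, 3), 4.8)
  z <- numeric(length(ft))
  for (o in onsets) {
    k <- findInterval(o, ft)
    idx <- k:(k + length(kern) - 1)
    z[idx] <- z[idx] + kern
  }
  s1 <- normalizedStf(z, ft, onsets)
  expect_true(all(abs(s1[is.finite(s1)] - 1) < 1e-9))
  # single-impulse response equals the kernel's 2 s discrete sum
  z2 <- numeric(length(ft))
  k <- findInterval(150, ft)
  z2[k:(k + length(kern) - 1)] <- kern
  raw <- normalizedStf(z2, ft, c(150, 30, 60, 90, 120))
  npost <- round(2 * 4.8)
  expect_equal(max(raw, na.rm = TRUE) *
                 quantile(vapply(c(150, 30, 60, 90, 120), function(o) {
                   i <- findInterval(o, ft)
                   sum(z2[i:(i + npost - 1)]) - npost * mean(z2[(i - 5):(i - 1)])
                 }, numeric(1)), 0.95, names = FALSE),
               sum(kern[seq_len(npost)]), tolerance = 1e-6)
  expect_error(normalizedStf(z, ft, c(10, 20)), ">= 5")
})

test_that("rectilinear fit recovers a hinge and prefers baseline for flat data", {
  x <- seq(0, 1, length.out = 60)
  y <- ifelse(x > 0.5, 2 * (x - 0.5), 0)
  f <- rectilinearFit(y, x)
  expect_true(f$ramp_accepted)
  expect_lt(abs(f$breakpoint - 0.5), 1 / 40 + 1e-9)   # within one grid step
  expect_lt(abs(f$slope - 2) / 2, 0.05)
  # flat data -> baseline only
  f0 <- rectilinearFit(rep(1, 30), seq(0, 1, length.out = 30))
  expect_false(f0$ramp_accepted)
  expect_true(is.na(f0$slope))
  # noisy hinge: ramp accepted and fits better than baseline alone
  set.seed(1)
  yn <- ifelse(x > 0.5, 2 * (x - 0.5), 0) + rnorm(60, 0, 0.1)
  fn <- rectilinearFit(yn, x)
  expect_true(fn$ramp_accepted)
  expect_lt(fn$mse, fn$mse_baseline_only)
  # selected-model MSE never exceeds baseline-only MSE
  for (sd in 1:5) {
    set.seed(sd)
    yy <- rnorm(40)
    ff <- rectilinearFit(yy, runif(40))
    expect_lte(ff$mse, ff$mse_baseline_only + 1e-12)
  }
  expect_error(rectilinearFit(1:5, 1:5), ">= 10")
})

test_that("saccade-type index separates kinematic and type coding", {
  # constructed events: conjugate and convergent saccades with overlapping
  # kinematics for the right eye
  set.seed(2)
  n <- 150
  mkev <- function(label, amp) {
    vel <- 700 * (1 - exp(-amp / 6)) * runif(n, 0.95, 1.05)
    data.frame(label = label, amp_r = -amp, med_post_r = -(amp - 2),
               vel_ccw_r = -vel, amp_l = 0, med_post_l = 0, vel_cw_l = 0)
  }
  conj <- mkev("ConjL", runif(n, 4, 12))
  conv <- mkev("ConvL", runif(n, 4, 12))
  ev <- rbind(conj, conv)
  # responses depending only on kinematics -> index ~ 0
  stf_kin <- 0.05 * (-ev$med_post_r) + rnorm(2 * n, 0, 0.01)
  r0 <- saccadeTypeIndex(stf_kin, ev, "right")
  expect_gte(r0$n_pairs, 100)
  expect_lt(abs(r0$index), 0.05)
  # responses set by type alone, +0.3 for convergent -> index exactly 0.3
  r3 <- saccadeTypeIndex(0.3 * grepl("^Conv", ev$label), ev, "right")
  expect_equal(r3$index, 0.3, tolerance = 1e-12)
  # no convergent saccade within the radius -> missing value
  conv_far <- mkev("ConvL", runif(n, 25, 30))
  ev2 <- rbind(conj, conv_far)
  r_na <- saccadeTypeIndex(stf_kin, ev2, "right")
  expect_true(is.na(r_na$index))
  expect_equal(r_na$n_pairs, 0L)
})

test_that("OKR power isolates direction-selective modulation", {
  ft <- seq(0.1, 200, by = 1 / 4.8)
  grat <- data.frame(t_start = seq(0, 188, by = 4),
                     t_end = seq(4, 192, by = 4),
                     direction = rep(c("L", "R"), length.out = 48))
  # direction-symmetric response -> zero power
  zsym <- sin(2 * pi * ft / 4)
  expect_lt(okrPower(zsym, ft, grat), 1e-20)
  # amplitude-a sinusoid at the alternation frequency -> power ~ a^2
  p1 <- okrPower(sin(2 * pi * ft / 8), ft, grat)
  p2 <- okrPower(2 * sin(2 * pi * ft / 8), ft, grat)
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
  # DC invariance
  expect_equal(okrPower(5 + sin(2 * pi * ft / 8), ft, grat), p1,
               tolerance = 1e-9)
  # modulated ROIs out-power broadband-noise ROIs in >= 95% of seeds
  wins <- vapply(1:20, function(sd) {
    set.seed(sd)
    zm <- 0.8 * sin(2 * pi * ft / 8) + rnorm(length(ft))
    zn <- rnorm(length(ft))
    okrPower(zm, ft, grat) > okrPower(zn, ft, grat)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  expect_error(okrPower(zsym, ft, NULL), "unknown")
})

test_that("PC1 score matches the closed-form 2-D solutions", {
  set.seed(3)
  z <- scale(rnorm(100))[, 1]
  # perfectly anticorrelated: PC1 explains all variance, scores (z1 - z2)/sqrt(2)
  p <- pc1Score(z, -z)
  expect_equal(p$var_explained, 1)
  expect_equal(p$scores, (z - (-z)) / sqrt(2) / sqrt(2) * sqrt(2),
               tolerance = 1e-8)
  expect_lt(abs(mean(p$scores)), 1e-10)
  # uncorrelated: both loadings 1/sqrt(2) in magnitude
  a <- rnorm(500); b <- rnorm(500)
  pu <- pc1Score(a, b)
  expect_equal(abs(unname(pu$loadings)), c(1, 1) / sqrt(2), tolerance = 0.1)
  expect_gt(pu$loadings["index"], 0)     # sign oriented to the index
  # duplicating every ROI leaves scores unchanged
  pd <- pc1Score(c(a, a), c(b, b))
  expect_equal(pd$scores[seq_along(a)], pu$scores, tolerance = 0.01)
  expect_error(pc1Score(rnorm(5), rnorm(5)), ">= 10")
})

test_that("directionality preference picks the more negative triple", {
  mk <- function(vals) {
    nm <- c("sacc_ConjL", "sacc_ConvGL", "eyepos_nasal_R",
            "sacc_ConjR", "sacc_ConvGR", "eyepos_nasal_L")
    data.frame(regressor = nm, shift = 1, cvR2_perm = 0,
               delta_cvR2 = vals)
  }
  d <- directionalityPreference(mk(c(-0.1, -0.05, -0.02, 0, 0, 0)))
  expect_equal(d$preference, "left")
  expect_equal(d$eye_for_nasal, "right")
  expect_false(d$tie)
  dt <- directionalityPreference(mk(rep(0, 6)))
  expect_true(dt$tie)
  expect_equal(dt$preference, "left")
  dr <- directionalityPreference(mk(c(0, 0, 0, -0.2, -0.1, 0)))
  expect_equal(dr$preference, "right")
  expect_equal(dr$eye_for_nasal, "left")
})

test_that("session-level tuning metrics are internally consistent", {
  ses <- fxSession()
  enc <- fxEncoding()
  m <- tuningMetrics(fxZF(), fxEvents(), enc, ses$stimuli$gratings)
  expect_true(all(c("saccade_type_index", "okr_power", "pc1_score") %in%
                  colnames(m)))
  # PC1 scores have zero mean across ROIs with both metrics
  ok <- is.finite(m$pc1_score)
  if (any(ok)) expect_lt(abs(mean(m$pc1_score[ok])), 1e-8)
  cls <- ses$truth$roi_class[match(m$roi, rownames(ses$fluor))]
  # convergent-specific cells carry higher indices than conjugate cells
  iconv <- median(m$saccade_type_index[cls == "mrmn_conv"], na.rm = TRUE)
  iconj <- median(m$saccade_type_index[cls %in% c("inn_like", "lrmn_like")],
                  na.rm = TRUE)
  expect_gt(iconv, iconj)
})
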