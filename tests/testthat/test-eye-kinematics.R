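# Saccade detection, onset refinement, measures and the nine-metric
# descriptor.

test_that("constant and too-short traces are handled", {
  t <- seq(0, 5, by = 1 / 300)
  tr <- EyeTrace(t, rep(1, length(t)), rep(1, length(t)))
  cand <- detectCoarse(tr)
  expect_length(cand$left, 0)
  expect_length(cand$right, 0)
  ts <- seq(0, 0.5, by = 1 / 300)
  expect_error(detectCoarse(EyeTrace(ts, ts, ts)), "1 s")
})

test_that("a noiseless step is located within 30 ms", {
  tr <- stepTrace(t_step = 5, amp = 10)
  cand <- detectCoarse(tr)
  expect_length(cand$left, 1)
  expect_lt(abs(cand$left - 5), 0.03)
})

test_that("steps 150 ms apart merge into one coarse event under the 1 Hz filter", {
  # the refractory discard would drop the second member of such a pair anyway
  t <- seq(0, 10, by = 1 / 300)
  x <- 8 * (t > 5) + 8 * (t > 5.15)
  cand <- detectCoarse(EyeTrace(t, x, x))
  hits <- cand$left[abs(cand$left - 5.1) < 0.5]
  expect_length(hits, 1)
})

test_that("pairing and refractory behave per the 100 ms / 300 ms rules", {
  # L@1.00, R@1.05 -> one binocular event
  ev <- pairAndRefractory(1.00, 1.05)
  expect_equal(nrow(ev), 1)
  expect_true(ev$binocular)
  # L@1.00, R@1.20 -> two monocular events; the later falls in the 300 ms
  # refractory of the first and is discarded
  ev2 <- pairAndRefractory(1.00, 1.20)
  expect_equal(nrow(ev2), 1)
  expect_false(ev2$binocular)
  expect_equal(ev2$time_s, 1.00)
  # single-eye event is retained as monocular
  ev3 <- pairAndRefractory(numeric(0), 2.5)
  expect_equal(nrow(ev3), 1)
  expect_false(ev3$binocular)
  expect_equal(ev3$time_r, 2.5)
  # empty input -> empty output
  expect_equal(nrow(pairAndRefractory(numeric(0), numeric(0))), 0)
})

test_that("refined onset is accurate and robust to noise", {
  tr <- stepTrace(t_step = 2, amp = 10, span = 6)
  on <- refineOnset(tr, 2, "left")
  expect_lt(abs(on - 2), 0.02)
  # pure-noise window: no saccade -> rejected
  set.seed(4)
  t <- seq(0, 6, by = 1 / 300)
  trn <- EyeTrace(t, rnorm(length(t), 0, 0.2), rnorm(length(t), 0, 0.2))
  expect_true(is.na(refineOnset(trn, 3, "left")))
  # 0.1 deg noise moves the onset of a 12 deg saccade by <= 10 ms
  base <- refineOnset(stepTrace(t_step = 3, amp = 12, noise = 0), 3, "left")
  shifts <- vapply(1:10, function(s) {
    trj <- stepTrace(t_step = 3, amp = 12, noise = 0.1, seed = s)
    refineOnset(trj, 3, "left") - base
  }, numeric(1))
  expect_lte(median(abs(shifts)), 0.010)
  # out-of-bounds window errors into NA
  expect_true(is.na(refineOnset(tr, 0.1, "left")))
})

test_that("per-eye measures follow their window definitions", {
  # clean 10 deg step: amplitude = med_post - pre = 10
  tr <- stepTrace(t_step = 5, amp = 10)
  m <- computeMeasures(tr, 5, "left")
  expect_lt(abs((m[["med_post"]] - m[["pre_pos"]]) - 10), 0.1)
  # linear ramp 10 deg/s: the derivative is 10 everywhere in the window, so
  # both the cw maximum and the ccw minimum equal the ramp velocity
  t <- seq(0, 10, by = 1 / 300)
  trr <- EyeTrace(t, 10 * t - 50, 10 * t - 50)
  mr <- computeMeasures(trr, 5, "left")
  expect_lt(abs(mr[["vel_cw"]] - 10), 1)
  expect_lt(abs(mr[["vel_ccw"]] - 10), 1)
  # overshoot: peak 12, settle 10 -> max_post 12, med_post 10
  dur <- 0.04
  x <- 12 * SaccadeFlow:::minJerk((t - 5) / dur) -
    2 * SaccadeFlow:::minJerk((t - 5 - dur) / 0.1)
  tro <- EyeTrace(t, x, x)
  mo <- computeMeasures(tro, 5, "left")
  expect_lt(abs(mo[["max_post"]] - 12), 0.15)
  expect_lt(abs(mo[["med_post"]] - 10), 0.15)
  expect_lt(abs((mo[["max_post"]] - mo[["med_post"]]) - 2), 0.3)
  # cw velocity never below ccw velocity
  expect_gte(m[["vel_cw"]], m[["vel_ccw"]])
  expect_gte(mo[["vel_cw"]], mo[["vel_ccw"]])
  # truncated window -> NULL
  expect_null(computeMeasures(tr, 0.05, "left"))
})

test_that("the event descriptor has nine metrics in a fixed order", {
  tr <- stepTrace(t_step = 5, amp = 10)
  m <- computeMeasures(tr, 5, "left")
  v <- nineMetrics(m, m)
  expect_length(v, 9)
  expect_identical(names(v), SaccadeFlow:::metricNames)
  # symmetric conjugate saccade: zero vergence
  expect_lt(abs(v[["vergence"]]), 1e-9)
  # convergent saccade, each eye 8 deg nasal: vergence = 16
  t <- seq(0, 10, by = 1 / 300)
  xl <- 8 * SaccadeFlow:::minJerk((t - 5) / 0.04)    # left eye rightward/nasal
  xr <- -8 * SaccadeFlow:::minJerk((t - 5) / 0.04)   # right eye leftward/nasal
  trc <- EyeTrace(t, xl, xr)
  vc <- nineMetrics(computeMeasures(trc, 5, "left"),
                    computeMeasures(trc, 5, "right"))
  expect_lt(abs(vc[["vergence"]] - 16), 0.1)
  # monocular event: available subset, missing entries NA
  vm <- nineMetrics(m, NULL)
  expect_true(all(is.na(vm[c("amp_r", "maxmed_r", "vel_cw_r", "vel_ccw_r",
                             "vergence")])))
  expect_false(anyNA(vm[c("amp_l", "maxmed_l", "vel_cw_l", "vel_ccw_l")]))
})

test_that("winsorized z-scoring normalizes per animal and flags flat columns", {
  set.seed(9)
  M <- cbind(a = rnorm(1e4), b = rep(3, 1e4))
  Mn <- normalizeMetrics(M)
  expect_lt(abs(mean(Mn[, "a"])), 0.05)
  expect_gt(sd(Mn[, "a"]), 0.95); expect_lt(sd(Mn[, "a"]), 1.05)
  expect_true(all(Mn[, "b"] == 0))
  expect_match(attr(Mn, "flat_columns"), "b", all = FALSE)
  # a single extreme outlier is clipped to the 99.5th percentile first
  x <- c(rnorm(999), 100)
  Mo <- normalizeMetrics(cbind(x = x))
  expect_lt(max(Mo), 4)      # without winsorizing the outlier would be ~> 30
  # per-animal grouping normalizes groups independently
  g <- rep(1:2, each = 500)
  x2 <- c(rnorm(500, 0, 1), rnorm(500, 50, 10))
  Mg <- normalizeMetrics(cbind(x = x2), animal = g)
  expect_lt(abs(mean(Mg[g == 2, ])), 0.1)
  expect_error(normalizeMetrics(cbind(x = 1:4), animal = c(1, 1, 1, 2)),
               ">= 2 events")
})

test_that("detection is deterministic and recovers a noiseless session exactly", {
  cfg <- sessionConfig(eye_noise_sd_deg = 0)
  sch <- makeSaccadeSchedule(25, 2.5, seed = 5)
  et <- generateEyeTraces(cfg, sch)
  ev1 <- detectSaccades(et$trace)
  ev2 <- detectSaccades(et$trace)
  expect_identical(ev1, ev2)
  # recall = precision = 1 against ground truth
  tt <- sch$saccades$time_s
  expect_equal(nrow(ev1), length(tt))
  err <- vapply(tt, function(t0) min(abs(ev1$onset_s - t0)), numeric(1))
  expect_true(all(err <= 0.05))
  # refined onset stays within the 400 ms refinement window of the coarse peak
  expect_true(all(abs(ev1$onset_s - ev1$coarse_peak_s) <= 0.4))
})
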