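# zF standardization, d-prime + permutation null, design construction, the
# OLS hyperparameter search, ridge CV and unique-variance attribution.

test_that("zF recovers baseline and noise and is affine-invariant", {
  set.seed(1)
  F <- matrix(rnorm(2e4, 10, 2), nrow = 2)
  fs <- computeZF(FluorescenceSet(F, seq_len(1e4), numeric(1e4)))
  z <- zF(fs)
  # (F - 10)/2 recovered within 10% at 1e4 frames
  expect_lt(abs(median(F[1, ]) - 10), 0.1)
  expect_lt(max(abs(z[1, ] - (F[1, ] - median(F[1, ])) / 2)) /
            max(abs(z[1, ])), 0.1)
  # affine invariance: zF(gF + b) == zF(F)
  fs2 <- computeZF(FluorescenceSet(3 * F + 7, seq_len(1e4), numeric(1e4)))
  expect_equal(zF(fs2), z, tolerance = 1e-10)
  # constant trace -> zero-noise flag
  fsc <- computeZF(FluorescenceSet(matrix(5, 1, 200), 1:200, numeric(200)))
  expect_equal(attr(fsc, "zero_noise"), 1L)
})

test_that("frames with motion error above 5 um are interpolated", {
  F <- matrix(7, 1, 200)
  me <- numeric(200); me[100] <- 6
  Fb <- F; Fb[1, 100] <- 50                       # corrupted frame
  fs <- computeZF(FluorescenceSet(Fb, 1:200, me))
  # interpolation of a constant restores the constant -> zF stays flat
  expect_true(all(abs(zF(fs)[1, ]) < 1e-6))
  expect_error(computeZF(FluorescenceSet(F, 1:200, rep(10, 200))), "all frames")
  expect_error(computeZF(FluorescenceSet(matrix(1, 1, 50), 1:50, numeric(50))),
               "100 frames")
})

test_that("d-prime matches its analytic form and is antisymmetric", {
  # post = pre + 2, unit variances -> d' = 2 in the population limit;
  # construct windows explicitly on a frame grid
  ft <- seq(0.5, 4000, by = 1)       # 1 Hz frames: pre window 1 frame, post 2
  set.seed(2)
  z <- rnorm(length(ft))
  onsets <- seq(10, 3990, by = 10)
  k <- findInterval(onsets, ft)
  post_idx <- as.vector(vapply(k, function(i) i:(i + 1), numeric(2)))
  z[post_idx] <- z[post_idx] + 2
  d <- saccadeDprime(z, ft, onsets)
  expect_lt(abs(d - 2), 0.1)
  # antisymmetry under swapping pre/post: shift onsets so windows exchange
  z2 <- -z
  d2 <- saccadeDprime(z2, ft, onsets)
  expect_lt(abs(d2 + d), 1e-9)
  # identical pre/post -> ~0
  set.seed(3)
  d0 <- saccadeDprime(rnorm(length(ft)), ft, onsets)
  expect_lt(abs(d0), 0.1)
  expect_error(saccadeDprime(z, ft, 10), ">= 2 events")
})

test_that("d-prime converges to 1 for unit-shift responses", {
  # post ~ N(1,1), pre ~ N(0,1), 200 events -> d' within 0.1 of 1
  set.seed(4)
  ft <- seq(0.5, 6000, by = 1)
  z <- rnorm(length(ft))
  onsets <- seq(15, 5985, by = 30)[1:200]
  k <- findInterval(onsets, ft)
  for (i in k) z[i:(i + 1)] <- z[i:(i + 1)] + 1
  expect_lt(abs(saccadeDprime(z, ft, onsets) - 1), 0.1)
})

test_that("the permutation null flags drivers and spares noise", {
  ses <- fxSession()
  enc <- fxEncoding()
  cls <- ses$truth$roi_class
  rois <- rownames(ses$fluor)
  # mrmn_both ROIs: Conv and at least one Conj type active
  for (r in rois[cls == "mrmn_both"][1:4]) {
    dp <- enc$dprime[[r]]
    expect_true(dp$active[dp$type == "Conv"])
    expect_true(any(dp$active[dp$type %in% c("LConj", "RConj")]))
  }
  # zero-variance ROI is never flagged
  ft <- frameTimes(ses$fluor)
  on <- list(Conv = ses$events$onset_s[grepl("^Conv", ses$events$label)])
  dp0 <- dprimeNullTest(rep(1, length(ft)), ft, on, n_shuffle = 200, seed = 1)
  expect_false(any(dp0$active))
})

test_that("design matrix structure is exactly 33 = 6 + 8 + 18 + 1", {
  ses <- fxSession()
  des <- ses$design
  expect_equal(ncol(designMatrix(des)), 33)
  expect_equal(as.vector(table(regressorGroups(des))), c(6, 8, 18, 1))
  expect_error(validObject(des), NA)
  # no swims: locomotor columns exist but are all zero
  ns <- buildDesign(ses$events, ses$trace,
                    data.frame(time_s = numeric(0), direction = character(0),
                               vigour = numeric(0)),
                    ses$stimuli, motionError(ses$fluor), frameTimes(ses$fluor))
  X <- designMatrix(ns)
  expect_equal(ncol(X), 33)
  expect_true(all(X[, grepl("^swim", colnames(X))] == 0))
  # a missing log names the absent predictor group
  expect_error(buildDesign(ses$events, ses$trace, NULL, ses$stimuli,
                           motionError(ses$fluor), frameTimes(ses$fluor)),
               "locomotor")
})

test_that("a single saccade onset column equals the placed CIRF kernel", {
  ft <- seq(0.1, 120, by = 1 / 4.8)
  tr <- EyeTrace(seq(0, 120, by = 0.01), numeric(12001), numeric(12001))
  ev <- data.frame(onset_s = 50, label = "ConjL")
  sw <- data.frame(time_s = 30, direction = "L", vigour = 1)
  stim <- list(gratings = data.frame(t_start = 1, t_end = 2, direction = "L"),
               spots = data.frame(t_start = 5, t_end = 6, direction = "R",
                                  contrast = 1, az_start = -76),
               spot_speed_dps = 30)
  cirf <- CIRF(0.2, 3)
  des <- buildDesign(ev, tr, sw, stim, numeric(length(ft)), ft, cirf,
                     offsetFrames = 0L)
  col <- designMatrix(des)[, "sacc_ConjL"]
  k0 <- which(col > 0)[1]
  kern <- cirfKernel(cirf, 4.8)
  expect_equal(col[k0:(k0 + length(kern) - 2)], kern[-1][seq_len(length(kern) - 1)],
               tolerance = 1e-9)
  # offset shifts the column by whole frames
  des2 <- buildDesign(ev, tr, sw, stim, numeric(length(ft)), ft, cirf,
                      offsetFrames = 2L)
  col2 <- designMatrix(des2)[, "sacc_ConjL"]
  expect_equal(col2[(k0 + 2):(k0 + 20)], col[k0:(k0 + 18)], tolerance = 1e-12)
})

test_that("the OLS search recovers hyperparameters and gates noise", {
  ses <- fxSession()
  fl <- fxZF()
  ft <- frameTimes(ses$fluor)
  designs <- designGrid(ses$events, ses$trace, ses$swims, ses$stimuli,
                        motionError(ses$fluor), ft)
  # noiseless generated ROI: near-perfect fit at the true pair
  X <- designMatrix(ses$design)
  Xn <- sweep(X, 2, pmax(apply(abs(X), 2, max), 1e-12), "/")
  # saccade-responsive ROI at the generator default weight scale and noise
  w <- setNames(numeric(ncol(Xn)), colnames(Xn))
  w[c("sacc_ConvGL", "sacc_ConvGR", "sacc_ConjL", "sacc_ConjR")] <- 2.5
  w["eyepos_nasal_R"] <- 0.5
  sig <- drop(Xn %*% w)
  s0 <- olsHyperparamSearch(sig, designs)
  expect_gte(s0$ols_r2, 0.999)
  expect_equal(s0$best_tau_off, 4)
  expect_equal(s0$best_offset, 2)
  # white-noise ROI fails the R2 > 0.05 gate
  set.seed(5)
  gates <- vapply(1:10, function(i)
    olsHyperparamSearch(rnorm(length(ft)), designs)$gate, logical(1))
  expect_lte(mean(gates), 0.05)
  # noisy recovery at generator SNR: >= 90% of draws
  set.seed(6)
  ok <- vapply(1:40, function(i) {
    y <- sig + rnorm(length(sig), 0, 1)
    s <- olsHyperparamSearch(y, designs)
    s$best_tau_off == 4 && s$best_offset == 2
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("ridge CV matches OLS at tiny lambda and shrinks monotonically", {
  set.seed(7)
  n <- 500; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% c(3, -2, 1.5, 0, 0, 0))
  f <- ridgeCvFit(y, X, lambda_grid = c(1e-8, 1))
  ols <- coef(lm(y ~ scale(X) - 1))
  expect_lt(max(abs(f$coefficients - ols)), 1e-6)
  yn <- y + rnorm(n)
  nrm <- vapply(c(1e-2, 1, 100, 1e4), function(l)
    sum(ridgeCvFit(yn, X, lambda_grid = l)$coefficients^2), numeric(1))
  expect_true(all(diff(nrm) < 0))
  # independent cross-check against MASS::lm.ridge on standardized data
  lam <- 5
  fr <- ridgeCvFit(yn, X, lambda_grid = lam)
  Xs <- scale(X); yc <- yn - mean(yn)
  bm <- solve(crossprod(Xs) + diag(lam, p), crossprod(Xs, yc))
  expect_equal(unname(fr$coefficients), unname(drop(bm)), tolerance = 1e-8)
  mr <- MASS::lm.ridge(yc ~ Xs - 1, lambda = lam)
  # lm.ridge scales by n-variance internally; compare direction
  expect_gt(cor(drop(coef(mr)), fr$coefficients), 0.999)
})

test_that("sign and rank of true coefficients are recovered", {
  ses <- fxSession()
  X <- designMatrix(ses$design)
  Xn <- sweep(X, 2, pmax(apply(abs(X), 2, max), 1e-12), "/")
  truth <- c(sacc_ConjL = 3, sacc_ConjR = -2, sacc_ConvGL = 1.2)
  sig <- drop(Xn[, names(truth)] %*% truth)
  set.seed(8)
  hits <- vapply(1:10, function(i) {
    y <- sig + rnorm(length(sig), 0, 1)
    fit <- ridgeCvFit(y, Xn)
    top <- sort(abs(fit$coefficients), decreasing = TRUE)[1:3]
    ord <- names(top)
    identical(ord, names(truth)) &&
      all(sign(fit$coefficients[names(truth)]) == sign(truth))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("circular permutation isolates unique contributions", {
  set.seed(9)
  n <- 600
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 2 * X[, 1] + rnorm(n, 0, 0.4)
  fit <- ridgeCvFit(y, X)
  d <- deltaCvR2(y, X, fit, seed = 1)
  # the sole driver collapses the fit; null regressors sit near zero
  expect_lt(d$delta_cvR2[1], -0.8 * fit$cvR2)
  expect_lt(max(abs(d$delta_cvR2[-1])), 0.02)
  expect_true(all(d$shift >= 10 & d$shift <= n - 10))
  # duplicated (collinear) regressors mask each other's unique contribution
  Xc <- cbind(X, x7 = X[, 1])
  fc <- ridgeCvFit(y, Xc)
  dc <- deltaCvR2(y, Xc, fc, seed = 1)
  expect_gt(dc$delta_cvR2[1], -0.05)
  expect_gt(dc$delta_cvR2[7], -0.05)
  # noiseless single-driver: permuted fit loses everything
  y0 <- 2 * X[, 2]
  f0 <- ridgeCvFit(y0, X, lambda_grid = 1e-6)
  d0 <- deltaCvR2(y0, X, f0, seed = 2)
  expect_lt(abs(d0$delta_cvR2[2] + f0$cvR2), 0.05)
})

test_that("the three-criterion classification labels tuned ROIs", {
  ses <- fxSession()
  enc <- fxEncoding()
  cls <- ses$truth$roi_class
  lab <- setNames(rep("none", nrow(ses$fluor)), rownames(ses$fluor))
  tn <- enc$tuned
  lab[tn$roi] <- ifelse(tn$tuned, tn$label, "none")
  ocu <- cls %in% c("mrmn_both", "mrmn_conv", "inn_like", "lrmn_like")
  expect_gte(mean(lab[ocu] != "none"), 0.9)                   # sensitivity
  expect_gte(mean(lab[cls == "motion_artifact"] == "none"), 0.9)
  expect_gte(mean(lab[cls == "locomotor"] == "none"), 0.9)    # specificity
  # label semantics follow the d' flags
  expect_true(all(lab[cls == "mrmn_both" & lab != "none"] == "Both"))
  expect_true(all(lab[cls == "mrmn_conv" & lab != "none"] == "Conv"))
  expect_error(classifyTuned(list(a = data.frame(regressor = "x", shift = 1,
                                                 cvR2_perm = 0.1,
                                                 delta_cvR2 = 0.01)),
                             list(), factor("oculomotor")),
               "pooled positive")
})

test_that("a locomotor-driven ROI fails criterion (i)", {
  ses <- fxSession()
  enc <- fxEncoding()
  cls <- ses$truth$roi_class
  loco <- rownames(ses$fluor)[cls == "locomotor"]
  gated <- intersect(loco, names(enc$delta))
  for (r in gated) {
    row <- enc$tuned[enc$tuned$roi == r, ]
    expect_false(row$crit1 && row$crit2 && row$crit3)
  }
})
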