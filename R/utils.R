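# Internal numerical helpers shared across modules.

# Resample a signal onto a uniform time base by linear interpolation.
resampleUniform <- function(t, x, rate_hz, t0 = t[1], t1 = t[length(t)]) {
  tu <- seq(t0, t1, by = 1 / rate_hz)
  list(t = tu, x = approx(t, x, xout = tu, rule = 2)$y)
}

# Displacement-equivalent step convolution: antisymmetric step kernel of
# total width `width_s` (-1 over the first half, +1 over the second),
# scaled so the response to an instantaneous position step equals the step
# amplitude. Output is aligned with the input samples (kernel centre).
stepConv <- function(x, width_s, rate_hz) {
  half <- max(1L, round(width_s * rate_hz / 2))
  k <- c(rep(-1, half), rep(1, half)) / half
  n <- length(x)
  # pad by edge replication so edges see zero displacement
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  y <- stats::filter(xp, rev(k), method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

# Indices of strict local maxima of x exceeding `thresh`.
localMaxima <- function(x, thresh = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  i[x[i] > thresh]
}

# Minimum-jerk unit step: s(0) = 0, s(1) = 1, peak slope 15/8 at tau = 1/2.
minJerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Duration (s) giving a minimum-jerk step of amplitude A its target peak
# velocity: peak vel = (15/8) * A / D.
minJerkDuration <- function(amplitude_deg, peak_vel_dps) {
  (15 / 8) * abs(amplitude_deg) / peak_vel_dps
}

# Main-sequence exponential: peak velocity as a function of amplitude.
mainSequenceVel <- function(A, Vmax, A0) Vmax * (1 - exp(-abs(A) / A0))

# Modal vote with summed-inverse-distance tie break; deterministic.
modalVote <- function(labels, dists) {
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  w <- vapply(top, function(lb) sum(1 / pmax(dists[labels == lb], 1e-12)),
              numeric(1))
  top[which.max(w)]
}

# Squared Euclidean distances from one point to rows of a matrix.
rowDist2 <- function(M, p) {
  d <- sweep(M, 2, p)
  rowSums(d * d)
}

# Derive a child seed (< 2^31) from a base seed and a stream index.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Robust high-frequency noise SD: first-difference estimator, exact for
# white Gaussian noise in expectation.
noiseSD <- function(x) {
  if (length(x) < 3) return(0)
  median(abs(diff(x))) / (sqrt(2) * qnorm(0.75))
}

# Gaussian AIC with k free mean parameters: n log(RSS/n) + 2k.
gaussAIC <- function(rss, n, k) n * log(rss / n) + 2 * k
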