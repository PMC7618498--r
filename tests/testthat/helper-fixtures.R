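# Shared fixtures, built once per test run and cached across test files.

.fx <- new.env(parent = emptyenv())

# Default 600 s synthetic session with ground truth.
fxSession <- function() {
  if (is.null(.fx$ses)) .fx$ses <- simulateSession(sessionConfig(rng_seed = 1L))
  .fx$ses
}

# Detected + classified + lateralized events for the shared session.
fxEvents <- function() {
  if (is.null(.fx$events)) {
    ses <- fxSession()
    ev <- detectSaccades(ses$trace)
    Mn <- normalizeMetrics(as.matrix(ev[, SaccadeFlow:::metricNames]))
    ev$label <- classifySaccades(Mn, fxReference())
    .fx$events <- lateralizeConvergent(ev)
  }
  .fx$events
}

fxReference <- function() {
  if (is.null(.fx$ref)) .fx$ref <- generateReferenceEmbedding(300, seed = 2L)
  .fx$ref
}

# Full encoding results on the shared session (ground-truth events).
fxEncoding <- function() {
  if (is.null(.fx$enc)) {
    ses <- fxSession()
    .fx$fl <- computeZF(ses$fluor)
    .fx$enc <- encodeSession(.fx$fl, ses$events, ses$trace, ses$swims,
                             ses$stimuli, seed = 3L)
  }
  .fx$enc
}

fxZF <- function() { fxEncoding(); .fx$fl }

# Match detected events back to scheduled ground truth by onset time.
matchTruth <- function(events, truth_times) {
  vapply(events$onset_s, function(o) which.min(abs(truth_times - o)), 1L)
}

# Simple minimum-jerk step trace for constructed-case tests.
stepTrace <- function(t_step = 5, amp = 10, dur = 0.04, rate = 300,
                      span = 10, noise = 0, seed = 1) {
  t <- seq(0, span, by = 1 / rate)
  x <- amp * SaccadeFlow:::minJerk((t - t_step) / dur)
  set.seed(seed)
  if (noise > 0) x <- x + rnorm(length(t), 0, noise)
  EyeTrace(t, x, x)
}
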