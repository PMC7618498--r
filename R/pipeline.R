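# Pipeline driver and plain-text session-bundle I/O.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis stages with its default.
#' Serializes losslessly to JSON; \code{\link{runPipeline}} records the exact
#' configuration (and a hash of it) in its result.
#'
#' @param seed master seed for every stochastic step.
#' @param detect_threshold_deg coarse detection threshold (deg).
#' @param n_shuffle d' null shuffles.
#' @param ref_n_per_type labeled points per type in the reference embedding.
#' @param classifier_backend "lda2d" or "metric9".
#' @param lambda_grid ridge penalty grid.
#' @param gate_r2 OLS gate.
#' @param ... overrides for any other stage parameter.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(seed = 1L, detect_threshold_deg = 1.5,
                           n_shuffle = 1000L, ref_n_per_type = 300L,
                           classifier_backend = "lda2d",
                           lambda_grid = 10^seq(-3, 3, by = 0.5),
                           gate_r2 = 0.05, ...) {
  cfg <- c(list(seed = as.integer(seed),
                detect_threshold_deg = detect_threshold_deg,
                n_shuffle = as.integer(n_shuffle),
                ref_n_per_type = as.integer(ref_n_per_type),
                classifier_backend = classifier_backend,
                lambda_grid = lambda_grid, gate_r2 = gate_r2), list(...))
  class(cfg) <- "PipelineConfig"
  cfg
}

configHash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small deterministic string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a session bundle
#'
#' detect -> normalize -> classify -> lateralize -> encode -> tuning metrics,
#' each stage failing with its name on error. Deterministic given the
#' configuration seed.
#'
#' @param bundle a session list as produced by \code{\link{simulateSession}}
#'   or \code{\link{readSessionBundle}} (trace, swims, stimuli, fluor).
#' @param config a \code{\link{pipelineConfig}}.
#' @return list(events, encoding, metrics, main_sequence, config,
#'   config_hash, seed).
#' @export
runPipeline <- function(bundle, config = pipelineConfig()) {
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  events <- stage("detect",
    detectSaccades(bundle$trace, config$detect_threshold_deg))
  if (nrow(events) == 0) stop("pipeline stage 'detect' found no events")
  M <- as.matrix(events[, metricNames])
  Mn <- stage("normalize", normalizeMetrics(M))
  ref <- stage("reference", generateReferenceEmbedding(
    config$ref_n_per_type, seed = config$seed,
    backend = config$classifier_backend))
  events$label <- stage("classify", classifySaccades(Mn, ref))
  events <- stage("lateralize", lateralizeConvergent(events))
  fl <- stage("zF", computeZF(bundle$fluor))
  enc <- stage("encode", encodeSession(fl, events, bundle$trace,
                                       bundle$swims, bundle$stimuli,
                                       seed = config$seed,
                                       n_shuffle = config$n_shuffle))
  metrics <- stage("metrics", if (length(enc$delta))
    tuningMetrics(fl, events, enc, bundle$stimuli$gratings) else NULL)
  ms <- stage("main_sequence", {
    adduct <- events$amp_l > 0 & !is.na(events$amp_l)
    conj <- grepl("^Conj", events$label)
    ok <- is.finite(events$amp_l) & is.finite(events$vel_cw_l) & adduct & conj
    if (sum(ok) >= 10)
      fitMainSequence(events$amp_l[ok], events$vel_cw_l[ok]) else NULL
  })
  list(events = events, encoding = enc, metrics = metrics,
       main_sequence = ms, config = config, config_hash = configHash(config),
       seed = config$seed)
}

#' Write / read a session bundle as plain text
#'
#' Eye trace, events, swims and stimuli as CSV; fluorescence and motion error
#' as CSV matrices; ground truth and config as JSON. Every file is
#' deterministic given the bundle.
#'
#' @param bundle session list from \code{\link{simulateSession}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSessionBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- bundle$trace
  utils::write.csv(data.frame(t_s = tr@t, left_deg = tr@left,
                              right_deg = tr@right),
                   file.path(dir, "eye_trace.csv"), row.names = FALSE)
  utils::write.csv(bundle$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(bundle$swims, file.path(dir, "swims.csv"), row.names = FALSE)
  utils::write.csv(bundle$stimuli$gratings, file.path(dir, "gratings.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stimuli$spots, file.path(dir, "spots.csv"),
                   row.names = FALSE)
  F <- SummarizedExperiment::assay(bundle$fluor, "F")
  utils::write.csv(data.frame(frame_t = frameTimes(bundle$fluor),
                              motion_error_um = motionError(bundle$fluor),
                              t(F)),
                   file.path(dir, "fluorescence.csv"), row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(list(saccades = truth$saccades,
                            ms_params = truth$ms_params,
                            roi_class = truth$roi_class,
                            cirf_tau_off = truth$cirf_tau_off,
                            offset_frames = truth$offset_frames,
                            spot_speed_dps = bundle$stimuli$spot_speed_dps),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSessionBundle
#' @export
readSessionBundle <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "eye_trace.csv"))
  fl <- utils::read.csv(file.path(dir, "fluorescence.csv"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  F <- t(as.matrix(fl[, -(1:2), drop = FALSE]))
  fluor <- FluorescenceSet(F, fl$frame_t, fl$motion_error_um,
                           rowData = if (!is.null(gt$roi_class))
                             data.frame(class = gt$roi_class) else NULL)
  list(trace = EyeTrace(tr$t_s, tr$left_deg, tr$right_deg),
       events = utils::read.csv(file.path(dir, "events.csv")),
       swims = utils::read.csv(file.path(dir, "swims.csv")),
       stimuli = list(gratings = utils::read.csv(file.path(dir, "gratings.csv")),
                      spots = utils::read.csv(file.path(dir, "spots.csv")),
                      spot_speed_dps = gt$spot_speed_dps),
       fluor = fluor, truth = gt)
}
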