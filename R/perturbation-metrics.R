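# Pre/post-manipulation behavioural metrics: ablation deficits, the
# convergent-minus-conjugate residual regression, and optogenetically evoked
# eye-position changes.

#' Ablation deficits
#'
#' Per eye and saccade category (convergent / conjugate, optionally split by
#' lateralization): median post-saccadic nasal position and nasal peak
#' velocity in each epoch; deficit = post-epoch median - pre-epoch median.
#' Cells with fewer than \code{min_events} saccades in either epoch are NA.
#'
#' @param pre,post labeled, measured event data.frames (one animal).
#' @param min_events minimum saccades per epoch per cell (default 5).
#' @param split_lateral also report ConvL/ConvR (and ConjL/ConjR) separately.
#' @return data.frame(eye, type, measure, pre_median, post_median, deficit).
#' @export
ablationDeficit <- function(pre, post, min_events = 5L, split_lateral = FALSE) {
  cats <- list(Conv = "^Conv", Conj = "^Conj")
  if (split_lateral)
    cats <- c(cats, list(ConvL = "^ConvL$", ConvR = "^ConvR$",
                         ConjL = "^ConjL$", ConjR = "^ConjR$"))
  rows <- list()
  for (eye in c("left", "right")) for (ct in names(cats)) {
    kin_pre <- nasalKinematics(pre[grepl(cats[[ct]], pre$label), ], eye)
    kin_post <- nasalKinematics(post[grepl(cats[[ct]], post$label), ], eye)
    for (ms in c("pos", "vel")) {
      a <- kin_pre[[ms]]; b <- kin_post[[ms]]
      enough <- sum(is.finite(a)) >= min_events && sum(is.finite(b)) >= min_events
      rows[[length(rows) + 1L]] <- data.frame(
        eye = eye, type = ct,
        measure = if (ms == "pos") "post_saccadic_position" else "peak_velocity",
        pre_median = if (enough) median(a, na.rm = TRUE) else NA_real_,
        post_median = if (enough) median(b, na.rm = TRUE) else NA_real_,
        deficit = if (enough) median(b, na.rm = TRUE) - median(a, na.rm = TRUE)
                  else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convergent-minus-conjugate residual regression
#'
#' Ordinary least squares of the per-animal Conv-Conj deficit residual on the
#' median saccade-type index of the manipulated cells, with R^2 and a
#' two-sided slope p value.
#'
#' @param residual Conv - Conj deficit per animal (deg), >= 4 animals.
#' @param median_index median saccade-type index of the ablated cells.
#' @return list(slope, intercept, r2, p_slope, n).
#' @export
convConjResidualRegression <- function(residual, median_index) {
  ok <- is.finite(residual) & is.finite(median_index)
  if (sum(ok) < 4) stop("need >= 4 animals")
  fit <- lm(residual[ok] ~ median_index[ok])
  sm <- suppressWarnings(summary(fit))   # perfect fits warn in summary.lm
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = sm$r.squared, p_slope = sm$coefficients[2, 4], n = sum(ok))
}

#' Optogenetically evoked eye-position change
#'
#' Per stimulation epoch and per eye: the difference between the median eye
#' position in the 250 ms window ending at stimulus offset and the 250 ms
#' window ending at stimulus onset. Invariant to adding a constant to the
#' trace.
#'
#' @param trace an \linkS4class{EyeTrace}.
#' @param epochs data.frame(t_start, t_end); epochs must last >= 0.5 s so the
#'   two windows do not overlap (>= 1 s recommended).
#' @return data.frame(t_start, t_end, change_left, change_right).
#' @export
optoPositionChange <- function(trace, epochs) {
  if (any(epochs$t_end - epochs$t_start < 0.5))
    stop("epochs shorter than 500 ms: onset and offset windows would overlap")
  medIn <- function(x, a, b) median(x[trace@t >= a & trace@t < b])
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    on <- epochs$t_start[i]; off <- epochs$t_end[i]
    if (on - 0.25 < trace@t[1] || off > trace@t[length(trace@t)] + 1e-9)
      stop("epoch windows fall outside the trace")
    data.frame(t_start = on, t_end = off,
               change_left = medIn(trace@left, off - 0.25, off) -
                 medIn(trace@left, on - 0.25, on),
               change_right = medIn(trace@right, off - 0.25, off) -
                 medIn(trace@right, on - 0.25, on))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired pre/post tests across animals
#'
#' Signed-rank (default) and paired t tests on a per-animal deficit measure.
#'
#' @param pre_medians,post_medians paired per-animal medians.
#' @return list(p_signed_rank, p_t).
#' @export
deficitTests <- function(pre_medians, post_medians) {
  list(p_signed_rank = suppressWarnings(
         wilcox.test(post_medians, pre_medians, paired = TRUE)$p.value),
       p_t = stats::t.test(post_medians, pre_medians, paired = TRUE)$p.value)
}
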