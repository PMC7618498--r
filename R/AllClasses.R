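#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData rowData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx median quantile sd var fft coef lm lm.fit predict
#'   rnorm runif rlnorm rpois rbinom wilcox.test prcomp qnorm setNames
#'   residuals
#' @importFrom utils head tail
NULL

# Sign convention used throughout: positive angle = rightward rotation, for
# both eyes, in a single head-fixed frame. Nasal direction is therefore
# positive for the left eye and negative for the right eye. Vergence =
# left - right; positive vergence = converged.

#' Binocular eye-position trace
#'
#' Timestamped horizontal eye angles for the left and right eye in a shared
#' head-fixed frame (positive = rightward rotation for both eyes; see
#' \code{convention}).
#'
#' @slot t numeric, strictly increasing sample times (seconds).
#' @slot left,right numeric, eye angles (degrees).
#' @slot convention single string describing the sign convention.
#' @export
setClass("EyeTrace",
  representation(t = "numeric", left = "numeric", right = "numeric",
                 convention = "character"),
  prototype(convention = "positive = rightward rotation, both eyes"))

setValidity("EyeTrace", function(object) {
  n <- length(object@t)
  if (length(object@left) != n || length(object@right) != n)
    return("t, left and right must have equal length")
  if (n > 1 && any(diff(object@t) <= 0))
    return("t must be strictly increasing")
  if (anyNA(object@t) || anyNA(object@left) || anyNA(object@right))
    return("EyeTrace must not contain NA values")
  TRUE
})

#' Construct an EyeTrace
#'
#' @param t sample times in seconds (strictly increasing).
#' @param left,right eye angles in degrees (positive = rightward).
#' @param convention sign-convention label stored with the object.
#' @return An \linkS4class{EyeTrace}.
#' @export
EyeTrace <- function(t, left, right,
                     convention = "positive = rightward rotation, both eyes") {
  new("EyeTrace", t = as.numeric(t), left = as.numeric(left),
      right = as.numeric(right), convention = convention)
}

#' @rdname EyeTrace
#' @param x an EyeTrace.
#' @export
traceTimes <- function(x) x@t

#' @rdname EyeTrace
#' @param eye "left" or "right".
#' @export
eyePosition <- function(x, eye = c("left", "right")) {
  eye <- match.arg(eye)
  if (eye == "left") x@left else x@right
}

setMethod("show", "EyeTrace", function(object) {
  n <- length(object@t)
  cat("EyeTrace:", n, "samples")
  if (n > 1)
    cat(sprintf(", %.1f s at ~%.0f Hz", diff(range(object@t)),
                (n - 1) / diff(range(object@t))))
  cat("\n  convention:", object@convention, "\n")
})

setMethod("length", "EyeTrace", function(x) length(x@t))

#' Calcium impulse response function
#'
#' Exponential rise-and-decay kernel, h(t) = (1 - exp(-t/tauOn)) *
#' exp(-t/tauOff) on t in [0, 5*tauOff], normalized to unit maximum.
#'
#' @slot tauOn,tauOff rise and decay time constants (seconds).
#' @export
setClass("CIRF", representation(tauOn = "numeric", tauOff = "numeric"),
         prototype(tauOn = 0.2, tauOff = 4))

setValidity("CIRF", function(object) {
  if (object@tauOn <= 0 || object@tauOff <= 0) return("time constants must be > 0")
  if (object@tauOff <= object@tauOn) return("tauOff must exceed tauOn")
  TRUE
})

#' @rdname CIRF-class
#' @param tauOn rise time constant (s), default 0.2.
#' @param tauOff decay time constant (s); the hyperparameter grid uses 3, 4, 5.
#' @export
CIRF <- function(tauOn = 0.2, tauOff = 4) new("CIRF", tauOn = tauOn, tauOff = tauOff)

setMethod("show", "CIRF", function(object)
  cat(sprintf("CIRF: tauOn = %.3g s, tauOff = %.3g s\n", object@tauOn, object@tauOff)))

#' Frame-aligned regressor design matrix
#'
#' Exactly 33 named columns: 6 oculomotor (4 saccade-onset one-hots + 2
#' rectified nasal eye-position traces), 8 locomotor (swim onsets by direction
#' x vigour quartile), 18 stimulus (2 grating directions + 16 moving-spot
#' azimuth x direction x contrast one-hots), all convolved with the CIRF and
#' shifted by \code{offsetFrames}, plus 1 unconvolved motion-error column.
#'
#' @slot X frame x regressor numeric matrix.
#' @slot groups factor with levels oculomotor/locomotor/stimulus/motion.
#' @slot cirf the \linkS4class{CIRF} used for convolution.
#' @slot offsetFrames integer temporal offset applied to the regressors.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", groups = "factor", cirf = "CIRF",
                 offsetFrames = "integer"))

setValidity("DesignMatrix", function(object) {
  if (ncol(object@X) != 33L) return("design must have exactly 33 columns")
  if (is.null(colnames(object@X))) return("design columns must be named")
  tab <- table(object@groups)
  want <- c(locomotor = 8L, motion = 1L, oculomotor = 6L, stimulus = 18L)
  if (!identical(as.integer(tab[names(want)]), unname(want)))
    return("group sizes must be oculomotor 6, locomotor 8, stimulus 18, motion 1")
  if (length(object@groups) != 33L) return("groups must tag all 33 columns")
  TRUE
})

#' @rdname DesignMatrix-class
#' @param x a DesignMatrix.
#' @export
designMatrix <- function(x) x@X

#' @rdname DesignMatrix-class
#' @export
regressorGroups <- function(x) x@groups

#' @rdname DesignMatrix-class
#' @export
regressorNames <- function(x) colnames(x@X)

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "frames x", ncol(object@X), "regressors\n")
  print(table(object@groups))
  cat(sprintf("  CIRF tauOff = %g s, offset = %d frames\n",
              object@cirf@tauOff, object@offsetFrames))
})

setMethod("dim", "DesignMatrix", function(x) dim(x@X))

#' Fluorescence container
#'
#' ROI x frame fluorescence wrapped in a
#' \link[SummarizedExperiment]{SummarizedExperiment}. Assay \code{"F"} holds
#' raw values; \code{\link{computeZF}} adds assay \code{"zF"}. Per-frame
#' metadata (\code{frame_t} seconds, \code{motion_error_um}) live in colData.
#'
#' @export
setClass("FluorescenceSet", contains = "SummarizedExperiment")

setValidity("FluorescenceSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("frame_t", "motion_error_um") %in% colnames(cd)))
    return("colData must contain frame_t and motion_error_um")
  ft <- cd$frame_t
  if (length(ft) > 1 && any(diff(ft) <= 0))
    return("frame_t must be strictly increasing")
  if (!("F" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'F' is required")
  TRUE
})

#' Construct a FluorescenceSet
#'
#' @param F ROI x frame matrix of raw fluorescence.
#' @param frame_t frame midpoint times (seconds), strictly increasing.
#' @param motion_error_um per-frame motion error (micrometres).
#' @param rowData optional per-ROI annotation (e.g. ground-truth class).
#' @return A \linkS4class{FluorescenceSet}.
#' @export
FluorescenceSet <- function(F, frame_t, motion_error_um, rowData = NULL) {
  stopifnot(ncol(F) == length(frame_t), length(frame_t) == length(motion_error_um))
  if (is.null(rownames(F))) rownames(F) <- sprintf("roi%03d", seq_len(nrow(F)))
  cd <- S4Vectors::DataFrame(frame_t = as.numeric(frame_t),
                             motion_error_um = as.numeric(motion_error_um))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(F = F), colData = cd)
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  new("FluorescenceSet", se)
}

#' @rdname FluorescenceSet
#' @param x a FluorescenceSet.
#' @export
frameTimes <- function(x) SummarizedExperiment::colData(x)$frame_t

#' @rdname FluorescenceSet
#' @export
motionError <- function(x) SummarizedExperiment::colData(x)$motion_error_um

#' @rdname FluorescenceSet
#' @export
zF <- function(x) {
  if (!("zF" %in% SummarizedExperiment::assayNames(x)))
    stop("zF not computed yet; run computeZF() first")
  SummarizedExperiment::assay(x, "zF")
}

#' Labeled 2-D reference embedding for saccade-type classification
#'
#' Holds labeled 2-D coordinates plus the fitted projection so new
#' normalized nine-metric vectors can be embedded and classified by the modal
#' label of their 100 nearest reference neighbours.
#'
#' @slot coords n x 2 matrix of embedded reference points.
#' @slot labels factor of saccade types (ConvL/ConvR/ConjL/ConjR).
#' @slot model fitted supervised projection (linear discriminant basis).
#' @slot backend "lda2d" (2-D discriminant embedding) or "metric9"
#'   (k-NN vote directly in the 9-D normalized metric space).
#' @export
setClass("ReferenceEmbedding",
  representation(coords = "matrix", labels = "factor", model = "list",
                 backend = "character"))

setValidity("ReferenceEmbedding", function(object) {
  if (nrow(object@coords) != length(object@labels))
    return("coords and labels must agree in length")
  if (nrow(object@coords) < 100L)
    return("reference embedding needs at least 100 points (modal 100-NN vote)")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  TRUE
})

setMethod("show", "ReferenceEmbedding", function(object) {
  cat("ReferenceEmbedding (", object@backend, "): ",
      nrow(object@coords), " labeled points\n", sep = "")
  print(table(object@labels))
})

#' Velocity main-sequence fit
#'
#' Exponential saturation model V = Vmax * (1 - exp(-A / A0)) relating
#' saccade peak velocity to amplitude.
#'
#' @slot Vmax saturation velocity (deg/s).
#' @slot A0 amplitude constant (deg).
#' @slot rss residual sum of squares; \code{aic} Gaussian AIC
#'   n*log(RSS/n) + 2k with k = 2.
#' @slot n number of saccades fitted; \code{converged} fit diagnostic flag.
#' @export
setClass("MainSequenceFit",
  representation(Vmax = "numeric", A0 = "numeric", rss = "numeric",
                 aic = "numeric", n = "integer", converged = "logical"))

setValidity("MainSequenceFit", function(object) {
  if (object@Vmax <= 0 || object@A0 <= 0) return("Vmax and A0 must be > 0")
  TRUE
})

setMethod("show", "MainSequenceFit", function(object)
  cat(sprintf("MainSequenceFit: Vmax = %.1f deg/s, A0 = %.2f deg (n = %d, AIC = %.1f%s)\n",
              object@Vmax, object@A0, object@n, object@aic,
              if (object@converged) "" else ", NOT converged")))
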