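#' @import methods
NULL

## Fixed ordering of the 14 texture statistics produced from a normalized
## co-occurrence matrix. Every feature table, model and CSV column layout in
## the package relies on this order.
.FEATURE_NAMES <- c(
  "autocorrelation", "contrast", "correlation", "dissimilarity",
  "energy", "entropy", "homogeneity", "maximum_probability",
  "mean", "variance", "sum_average", "sum_variance",
  "sum_entropy", "difference_entropy"
)

## The three diagnostic classes, in fixed order. Argmax ties are broken
## towards the earlier class.
.CLASS_LABELS <- c("normal", "benign", "malignant")

#' Ordered names of the 14 texture features
#'
#' Returns the fixed feature ordering used by [textureFeatures()],
#' [writeFeatureTable()] and [AnfisModel-class] objects.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' textureFeatureNames()
textureFeatureNames <- function() .FEATURE_NAMES

#' Ordered diagnostic class labels
#'
#' @return `c("normal", "benign", "malignant")` — the fixed class order used
#'   for argmax tie-breaking and for confusion-matrix layout.
#' @export
classLabels <- function() .CLASS_LABELS

# ---------------------------------------------------------------------------
# GreyImage
# ---------------------------------------------------------------------------

#' GreyImage: a quantized grey-scale image
#'
#' The universal pipeline currency: a 2-D grid of integer intensities with a
#' known number of grey levels `G`. Pixels are stored as an integer matrix
#' in (row, col) order with row 1 at the top; every intensity `i` satisfies
#' `0 <= i < levels`.
#'
#' @slot pixels Integer matrix of intensities.
#' @slot levels Integer, the number of grey levels `G` (`>= 2`).
#'
#' @seealso [greyImage()], [readGreyImage()], [quantize()]
#' @export
setClass("GreyImage",
  representation(pixels = "matrix", levels = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
    if (length(object@levels) != 1L || is.na(object@levels) ||
        object@levels < 2L) {
      return("levels must be a single integer >= 2")
    }
    if (anyNA(p)) return("pixels must not contain NA")
    if (any(p != floor(p))) return("pixels must be integral")
    if (min(p) < 0 || max(p) >= object@levels) {
      return(sprintf("intensities must lie in [0, %d]", object@levels - 1L))
    }
    TRUE
  }
)

#' Construct a GreyImage
#'
#' @param pixels Numeric matrix of integral intensities, row 1 at the top.
#' @param levels Number of grey levels `G`; intensities must lie in
#'   `0..levels-1`. Default 256 (8-bit).
#' @return A [GreyImage-class] object.
#' @export
#' @examples
#' img <- greyImage(matrix(0:3, 2, 2), levels = 4)
#' greyLevels(img)
greyImage <- function(pixels, levels = 256L) {
  storage.mode(pixels) <- "integer"
  new("GreyImage", pixels = pixels, levels = as.integer(levels))
}

#' @describeIn GreyImage-class image dimensions `(rows, cols)`
#' @param x a `GreyImage`
#' @export
setMethod("dim", "GreyImage", function(x) dim(x@pixels))

setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Extract the pixel grid
#'
#' @param x A [GreyImage-class] or [BinaryMask-class].
#' @return The underlying integer matrix.
#' @export
setMethod("pixels", "GreyImage", function(x) x@pixels)

setGeneric("greyLevels", function(x) standardGeneric("greyLevels"))

#' Number of grey levels of an image
#'
#' @param x A [GreyImage-class].
#' @return Integer `G`.
#' @export
setMethod("greyLevels", "GreyImage", function(x) x@levels)

setMethod("show", "GreyImage", function(object) {
  cat(sprintf(
    "GreyImage: %d x %d pixels, %d grey levels (range %d..%d)\n",
    nrow(object@pixels), ncol(object@pixels), object@levels,
    min(object@pixels), max(object@pixels)
  ))
})

# ---------------------------------------------------------------------------
# BinaryMask
# ---------------------------------------------------------------------------

#' BinaryMask: a foreground/background segmentation mask
#'
#' Pixels are exactly 0 (background, rendered black) or 1 (foreground,
#' rendered white), with the same (row, col) convention as
#' [GreyImage-class].
#'
#' @slot pixels Integer matrix of 0/1 values.
#' @seealso [binaryMask()], [globalThreshold()], [segmentTumor()]
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("mask must be at least 1x1")
    if (anyNA(p) || !all(p %in% c(0L, 1L))) {
      return("mask values must be exactly 0 or 1")
    }
    TRUE
  }
)

#' Construct a BinaryMask
#'
#' @param pixels Matrix of 0/1 values (logical matrices are accepted).
#' @return A [BinaryMask-class] object.
#' @export
binaryMask <- function(pixels) {
  if (is.logical(pixels)) {
    pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  }
  storage.mode(pixels) <- "integer"
  new("BinaryMask", pixels = pixels)
}

#' @describeIn BinaryMask-class mask dimensions
#' @param x a `BinaryMask`
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

#' @describeIn BinaryMask-class the underlying 0/1 matrix
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf(
    "BinaryMask: %d x %d, %d foreground pixels (%.1f%%)\n",
    nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
    100 * mean(object@pixels)
  ))
})

# ---------------------------------------------------------------------------
# CooccurrenceMatrix
# ---------------------------------------------------------------------------

#' CooccurrenceMatrix: grey-level pair frequencies at a fixed offset
#'
#' A `G x G` matrix whose `(a+1, b+1)` entry counts pixel pairs
#' `(p, p + offset)` with intensities `a` and `b`; `probs` holds the
#' normalized relative frequencies (summing to 1). The four supported
#' orientations map to (row, col) offsets `0 -> (0, +d)`, `45 -> (-d, +d)`,
#' `90 -> (-d, 0)` and `135 -> (-d, -d)`; the angle `"avg"` marks the
#' element-wise mean of the four orientation matrices.
#'
#' @slot counts Numeric `G x G` matrix of raw pair counts (may be non-integer
#'   for averaged matrices).
#' @slot probs Numeric `G x G` matrix of relative frequencies.
#' @slot offset Integer `(drow, dcol)` pair (`NA` for averaged matrices).
#' @slot distance Positive integer pixel distance `d`.
#' @slot angle One of `"0"`, `"45"`, `"90"`, `"135"`, `"avg"`.
#' @slot symmetric Logical; if `TRUE` each pair was counted in both
#'   directions.
#' @slot levels Integer `G`.
#' @seealso [cooccurrence()], [averageMatrix()], [textureFeatures()]
#' @export
setClass("CooccurrenceMatrix",
  representation(
    counts = "matrix", probs = "matrix", offset = "integer",
    distance = "integer", angle = "character", symmetric = "logical",
    levels = "integer"
  ),
  validity = function(object) {
    G <- object@levels
    if (!identical(dim(object@counts), c(G, G)) ||
        !identical(dim(object@probs), c(G, G))) {
      return("counts and probs must both be G x G")
    }
    if (any(object@counts < 0)) return("counts must be non-negative")
    tot <- sum(object@counts)
    if (tot > 0 && abs(sum(object@probs) - 1) > 1e-8) {
      return("probs must sum to 1 for a non-empty matrix")
    }
    if (!object@angle %in% c("0", "45", "90", "135", "avg")) {
      return("angle must be one of 0, 45, 90, 135, avg")
    }
    if (object@symmetric && object@angle != "avg" &&
        !isTRUE(all.equal(object@counts, t(object@counts)))) {
      return("symmetric matrix must equal its transpose")
    }
    TRUE
  }
)

setGeneric("glcmProbs", function(x) standardGeneric("glcmProbs"))
setGeneric("glcmCounts", function(x) standardGeneric("glcmCounts"))

#' Normalized probabilities of a co-occurrence matrix
#' @param x A [CooccurrenceMatrix-class].
#' @return Numeric `G x G` matrix summing to 1.
#' @export
setMethod("glcmProbs", "CooccurrenceMatrix", function(x) x@probs)

#' Raw pair counts of a co-occurrence matrix
#' @param x A [CooccurrenceMatrix-class].
#' @return Numeric `G x G` matrix of counts.
#' @export
setMethod("glcmCounts", "CooccurrenceMatrix", function(x) x@counts)

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf(
    "CooccurrenceMatrix: %d levels, d=%d, angle=%s%s, %g pairs\n",
    object@levels, object@distance, object@angle,
    if (object@symmetric) " (symmetric)" else "", sum(object@counts)
  ))
})

# ---------------------------------------------------------------------------
# TextureFeatures
# ---------------------------------------------------------------------------

#' TextureFeatures: the 14-value texture statistic vector
#'
#' Holds the 14 named, unitless texture statistics computed from one
#' normalized co-occurrence matrix, in the fixed order given by
#' [textureFeatureNames()].
#'
#' @slot values Named numeric vector of length 14.
#' @seealso [textureFeatures()], [extractFeatures()]
#' @export
setClass("TextureFeatures",
  representation(values = "numeric"),
  validity = function(object) {
    if (length(object@values) != length(.FEATURE_NAMES)) {
      return("exactly 14 feature values required")
    }
    if (!identical(names(object@values), .FEATURE_NAMES)) {
      return("feature names/order must match textureFeatureNames()")
    }
    if (anyNA(object@values)) return("feature values must not be NA")
    TRUE
  }
)

setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Numeric values of a texture feature vector
#' @param x A [TextureFeatures-class].
#' @return Named numeric vector of length 14.
#' @export
setMethod("featureValues", "TextureFeatures", function(x) x@values)

setMethod("show", "TextureFeatures", function(object) {
  cat("TextureFeatures (14 statistics):\n")
  print(round(object@values, 4))
})

# ---------------------------------------------------------------------------
# GlcmMarginals
# ---------------------------------------------------------------------------

#' GlcmMarginals: marginal moments of a co-occurrence distribution
#'
#' Row/column marginal means and probability-weighted variances of a
#' normalized co-occurrence matrix, over the level indices `0..G-1`.
#'
#' @slot meanRow,meanCol Marginal means.
#' @slot varRow,varCol Marginal variances (`>= 0`).
#' @seealso [marginalStats()]
#' @export
setClass("GlcmMarginals",
  representation(
    meanRow = "numeric", meanCol = "numeric",
    varRow = "numeric", varCol = "numeric"
  ),
  validity = function(object) {
    if (object@varRow < 0 || object@varCol < 0) {
      return("marginal variances must be non-negative")
    }
    TRUE
  }
)

setMethod("show", "GlcmMarginals", function(object) {
  cat(sprintf(
    "GlcmMarginals: mean (row %.4g, col %.4g), var (row %.4g, col %.4g)\n",
    object@meanRow, object@meanCol, object@varRow, object@varCol
  ))
})

# ---------------------------------------------------------------------------
# SegmentationResult
# ---------------------------------------------------------------------------

#' SegmentationResult: mask plus intermediates of tumour segmentation
#'
#' Retains every stage of [segmentTumor()]: the raw binarization at the
#' concentration threshold, the mask after morphological closing, the mask
#' after hole filling, and the final mask (optionally the largest connected
#' component only).
#'
#' @slot threshold Intensity threshold actually used.
#' @slot maskThreshold,maskMorph,maskFilled,final [BinaryMask-class] stages.
#' @export
setClass("SegmentationResult",
  representation(
    threshold = "integer", maskThreshold = "BinaryMask",
    maskMorph = "BinaryMask", maskFilled = "BinaryMask",
    final = "BinaryMask"
  ),
  validity = function(object) {
    if (any(object@maskFilled@pixels < object@maskMorph@pixels)) {
      return("hole filling may only add foreground pixels")
    }
    TRUE
  }
)

setGeneric("finalMask", function(x) standardGeneric("finalMask"))

#' Final mask of a segmentation result
#' @param x A [SegmentationResult-class].
#' @return The final [BinaryMask-class].
#' @export
setMethod("finalMask", "SegmentationResult", function(x) x@final)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: threshold=%d, final foreground %d px\n",
    object@threshold, sum(object@final@pixels)
  ))
})

# ---------------------------------------------------------------------------
# AnfisModel
# ---------------------------------------------------------------------------

#' AnfisModel: an adaptive neuro-fuzzy classifier
#'
#' A zero-order Takagi--Sugeno fuzzy system: per-feature Gaussian membership
#' functions (fuzzification), rules combining one membership function per
#' feature by the product t-norm, normalized firing strengths, and per-class
#' scores as firing-strength-weighted averages of rule consequent weights
#' (defuzzification). Inputs are z-score standardized with statistics stored
#' in the model. All parameters are trained by batch gradient descent with
#' momentum (see [trainAnfis()]).
#'
#' @slot featureNames Ordered input feature names.
#' @slot classes Ordered class labels (ties at argmax break to the earlier
#'   class).
#' @slot centers,widths Lists (one element per feature) of numeric vectors:
#'   the Gaussian membership centers and widths (widths `> 0`), in
#'   standardized feature units.
#' @slot rules Integer matrix, one row per rule, one column per feature; the
#'   entry is the index of that feature's membership function in the rule's
#'   antecedent.
#' @slot consequents Numeric matrix, one row per rule, one column per class.
#' @slot standardizeMean,standardizeSd Per-feature z-score statistics.
#' @slot learningRate Positive step size `eta`.
#' @slot momentum Momentum coefficient `rho` in `[0, 1)` (the fraction of
#'   the previous update carried into the current one).
#' @slot seed Integer RNG seed all stochastic choices flow from.
#' @slot version Model schema version tag.
#' @seealso [anfisModel()], [initAnfis()], [trainAnfis()], [predictScores()]
#' @export
setClass("AnfisModel",
  representation(
    featureNames = "character", classes = "character",
    centers = "list", widths = "list", rules = "matrix",
    consequents = "matrix", standardizeMean = "numeric",
    standardizeSd = "numeric", learningRate = "numeric",
    momentum = "numeric", seed = "integer", version = "character"
  ),
  validity = function(object) {
    nf <- length(object@featureNames)
    nc <- length(object@classes)
    if (length(object@centers) != nf || length(object@widths) != nf) {
      return("centers and widths need one element per feature")
    }
    for (f in seq_len(nf)) {
      if (length(object@centers[[f]]) != length(object@widths[[f]])) {
        return("each feature needs matching numbers of centers and widths")
      }
      if (any(object@widths[[f]] <= 0)) return("widths must be positive")
    }
    if (ncol(object@rules) != nf) {
      return("rules must have one column per feature")
    }
    for (f in seq_len(nf)) {
      idx <- object@rules[, f]
      if (any(idx < 1L | idx > length(object@centers[[f]]))) {
        return("rule antecedent indices out of range")
      }
    }
    if (!identical(dim(object@consequents),
                   c(nrow(object@rules), nc))) {
      return("consequents must be rules x classes")
    }
    if (length(object@standardizeMean) != nf ||
        length(object@standardizeSd) != nf ||
        any(object@standardizeSd <= 0)) {
      return("standardization statistics must be per-feature with sd > 0")
    }
    if (object@momentum < 0 || object@momentum >= 1) {
      return("momentum must lie in [0, 1)")
    }
    if (object@learningRate <= 0) return("learningRate must be positive")
    TRUE
  }
)

setMethod("show", "AnfisModel", function(object) {
  cat(sprintf(
    "AnfisModel: %d features, %d rules, classes {%s}\n  eta=%g, rho=%g, %d MFs/feature (median), schema %s\n",
    length(object@featureNames), nrow(object@rules),
    paste(object@classes, collapse = ", "), object@learningRate,
    object@momentum, stats::median(lengths(object@centers)),
    object@version
  ))
})

# ---------------------------------------------------------------------------
# TrainingTrace
# ---------------------------------------------------------------------------

#' TrainingTrace: per-epoch objective values of a training run
#'
#' @slot errors Non-negative per-epoch total squared-error loss.
#' @slot finalEpoch Number of epochs actually run.
#' @seealso [trainAnfis()]
#' @export
setClass("TrainingTrace",
  representation(errors = "numeric", finalEpoch = "integer"),
  validity = function(object) {
    if (any(object@errors < 0)) return("loss values must be non-negative")
    if (object@finalEpoch != length(object@errors)) {
      return("finalEpoch must equal the number of recorded epochs")
    }
    TRUE
  }
)

setGeneric("traceErrors", function(x) standardGeneric("traceErrors"))

#' Per-epoch loss values of a training trace
#' @param x A [TrainingTrace-class].
#' @return Numeric vector of per-epoch losses.
#' @export
setMethod("traceErrors", "TrainingTrace", function(x) x@errors)

setMethod("show", "TrainingTrace", function(object) {
  cat(sprintf(
    "TrainingTrace: %d epochs, loss %.6g -> %.6g\n",
    object@finalEpoch, object@errors[1L],
    object@errors[object@finalEpoch]
  ))
})
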