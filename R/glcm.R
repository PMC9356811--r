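## (drow, dcol) offset for an orientation at distance d, in the package's
## (row, col) convention with row 1 at the top:
##   0 deg -> (0, +d); 45 deg -> (-d, +d); 90 deg -> (-d, 0);
##   135 deg -> (-d, -d).
.glcmOffset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("'angle' must be one of 0, 45, 90, 135")
  )
}

#' Grey-level co-occurrence matrix at one orientation
#'
#' Counts, over all pixel pairs `(p, p + offset)` lying inside the image,
#' how often intensity `a` co-occurs with intensity `b`, and normalizes the
#' counts to relative frequencies. With `symmetric = TRUE` (the default)
#' each pair is also counted in the reversed direction, so the matrix equals
#' its transpose.
#'
#' @param image A [GreyImage-class]; its `levels` determines the matrix
#'   size `G`.
#' @param distance Positive integer pixel distance `d`.
#' @param angle Orientation in degrees: 0, 45, 90 or 135.
#' @param symmetric Count each pair in both directions (default `TRUE`).
#' @return A [CooccurrenceMatrix-class].
#' @export
#' @examples
#' img <- greyImage(rbind(c(0, 0), c(1, 1)), levels = 2)
#' glcmProbs(cooccurrence(img, 1, 0))
cooccurrence <- function(image, distance = 1L, angle = 0,
                         symmetric = TRUE) {
  stopifnot(is(image, "GreyImage"))
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) {
    stop("'distance' must be a positive integer")
  }
  off <- .glcmOffset(angle, distance)
  p <- image@pixels
  G <- image@levels
  nr <- nrow(p); nc <- ncol(p)
  r0 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
  c0 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
  if (r0[1L] > r0[length(r0)] || c0[1L] > c0[length(c0)] ||
      abs(off[1L]) >= nr || abs(off[2L]) >= nc) {
    stop("offset larger than image: no valid pixel pairs")
  }
  a <- p[r0, c0, drop = FALSE]
  b <- p[r0 + off[1L], c0 + off[2L], drop = FALSE]
  counts <- matrix(
    tabulate(as.vector(a) * G + as.vector(b) + 1L, nbins = G * G),
    G, G, byrow = TRUE
  )
  counts <- counts * 1.0
  if (symmetric) counts <- counts + t(counts)
  new("CooccurrenceMatrix",
    counts = counts, probs = counts / sum(counts),
    offset = off, distance = distance,
    angle = as.character(angle), symmetric = isTRUE(symmetric),
    levels = G
  )
}

#' Element-wise average of the four orientation matrices
#'
#' Forms the fifth co-occurrence matrix as the element-wise mean of the
#' 0, 45, 90 and 135 degree matrices; the result still sums to 1 and is
#' tagged with angle `"avg"`.
#'
#' @param mats List of four [CooccurrenceMatrix-class] objects sharing
#'   levels, distance and symmetry flag.
#' @return A [CooccurrenceMatrix-class] with `angle = "avg"`.
#' @export
averageMatrix <- function(mats) {
  if (length(mats) != 4L ||
      !all(vapply(mats, is, logical(1L), "CooccurrenceMatrix"))) {
    stop("'mats' must be a list of 4 CooccurrenceMatrix objects")
  }
  G <- mats[[1L]]@levels
  d <- mats[[1L]]@distance
  s <- mats[[1L]]@symmetric
  for (m in mats[-1L]) {
    if (m@levels != G) stop("all matrices must share the same levels")
    if (m@distance != d || m@symmetric != s) {
      stop("all matrices must share distance and symmetry flag")
    }
  }
  probs <- Reduce(`+`, lapply(mats, function(m) m@probs)) / 4
  counts <- Reduce(`+`, lapply(mats, function(m) m@counts)) / 4
  new("CooccurrenceMatrix",
    counts = counts, probs = probs, offset = c(NA_integer_, NA_integer_),
    distance = d, angle = "avg", symmetric = s, levels = G
  )
}

#' Marginal moments of a co-occurrence distribution
#'
#' Forms the row and column marginal distributions of the normalized matrix
#' and returns their probability-weighted means and variances over the grey
#' levels `0..G-1`: `meanRow = sum_a a p_r(a)`,
#' `varRow = sum_a (a - meanRow)^2 p_r(a)`, likewise for columns. For a
#' symmetric matrix the row and column moments coincide.
#'
#' @param P A [CooccurrenceMatrix-class] whose `probs` sums to 1.
#' @return A [GlcmMarginals-class].
#' @export
marginalStats <- function(P) {
  stopifnot(is(P, "CooccurrenceMatrix"))
  pr <- P@probs
  tot <- sum(pr)
  if (tot <= 0) stop("degenerate all-zero co-occurrence matrix")
  lv <- 0:(P@levels - 1L)
  prow <- rowSums(pr)
  pcol <- colSums(pr)
  mr <- sum(lv * prow)
  mc <- sum(lv * pcol)
  new("GlcmMarginals",
    meanRow = mr, meanCol = mc,
    varRow = sum((lv - mr)^2 * prow),
    varCol = sum((lv - mc)^2 * pcol)
  )
}

#' The 14 texture statistics of a co-occurrence matrix
#'
#' Computes, from the normalized probabilities `p(a, b)` over levels
#' `a, b = 0..G-1`, the fixed 14-feature vector (order given by
#' [textureFeatureNames()]):
#' \describe{
#'   \item{autocorrelation}{`sum a b p(a,b)`}
#'   \item{contrast}{`sum (a-b)^2 p(a,b)`}
#'   \item{correlation}{`(autocorrelation - mu_r mu_c) / (sigma_r sigma_c)`;
#'     reported as 0 with a warning when a marginal variance is zero}
#'   \item{dissimilarity}{`sum |a-b| p(a,b)`}
#'   \item{energy}{angular second moment `sum p^2`}
#'   \item{entropy}{`-sum_{p>0} p log p` (natural log by default)}
#'   \item{homogeneity}{inverse difference moment
#'     `sum p(a,b) / (1 + (a-b)^2)`}
#'   \item{maximum_probability}{`max p`}
#'   \item{mean, variance}{row-marginal mean and variance (see
#'     [marginalStats()])}
#'   \item{sum_average, sum_variance, sum_entropy}{moments and entropy of
#'     the level-sum distribution `p_{a+b}`}
#'   \item{difference_entropy}{entropy of the absolute level-difference
#'     distribution `p_{|a-b|}`}
#' }
#'
#' @param P A [CooccurrenceMatrix-class].
#' @param base Logarithm base for the entropy-type features (default
#'   `exp(1)`, natural log).
#' @return A [TextureFeatures-class].
#' @export
textureFeatures <- function(P, base = exp(1)) {
  stopifnot(is(P, "CooccurrenceMatrix"))
  pr <- P@probs
  if (sum(pr) <= 0) stop("degenerate all-zero co-occurrence matrix")
  G <- P@levels
  lv <- 0:(G - 1L)
  A <- matrix(lv, G, G)        # row level index a
  B <- matrix(lv, G, G, byrow = TRUE)  # col level index b
  ms <- marginalStats(P)

  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q, base = base))
  }

  autoc <- sum(A * B * pr)
  if (ms@varRow > 0 && ms@varCol > 0) {
    corr <- (autoc - ms@meanRow * ms@meanCol) /
      sqrt(ms@varRow * ms@varCol)
  } else {
    warning("zero marginal variance: correlation reported as 0")
    corr <- 0
  }

  ## distribution of the level sum a+b (support 0 .. 2G-2) and of the
  ## absolute level difference |a-b| (support 0 .. G-1)
  psum <- vapply(0:(2L * G - 2L),
                 function(k) sum(pr[A + B == k]), numeric(1L))
  pdiff <- vapply(0:(G - 1L),
                  function(k) sum(pr[abs(A - B) == k]), numeric(1L))
  sumAvg <- sum((0:(2L * G - 2L)) * psum)

  vals <- c(
    autocorrelation = autoc,
    contrast = sum((A - B)^2 * pr),
    correlation = corr,
    dissimilarity = sum(abs(A - B) * pr),
    energy = sum(pr^2),
    entropy = ent(pr),
    homogeneity = sum(pr / (1 + (A - B)^2)),
    maximum_probability = max(pr),
    mean = ms@meanRow,
    variance = ms@varRow,
    sum_average = sumAvg,
    sum_variance = sum(((0:(2L * G - 2L)) - sumAvg)^2 * psum),
    sum_entropy = ent(psum),
    difference_entropy = ent(pdiff)
  )
  new("TextureFeatures", values = vals)
}

#' Extract texture features from an image
#'
#' Quantizes the image to `levels` grey levels, builds the four orientation
#' co-occurrence matrices (0, 45, 90, 135 degrees) and their element-wise
#' average — five matrices in all — and evaluates the 14 texture statistics
#' on the requested matrices. Deterministic for a fixed input.
#'
#' @param image A [GreyImage-class].
#' @param levels Grey levels `G` for quantization (default 8, common
#'   Haralick practice).
#' @param distance Pixel distance `d` (default 1).
#' @param symmetric Symmetric pair counting (default `TRUE`).
#' @param which `"averaged"` returns the feature vector of the averaged
#'   matrix only; `"per-orientation"` the four orientation vectors;
#'   `"all"` all five (named `a0, a45, a90, a135, avg`).
#' @return For `"averaged"` a single [TextureFeatures-class]; otherwise a
#'   named list of [TextureFeatures-class] objects.
#' @export
#' @examples
#' img <- greyImage(matrix(rep(c(0, 255), length.out = 64), 8, 8), 256)
#' fv <- extractFeatures(img, levels = 8, which = "averaged")
#' featureValues(fv)[["contrast"]]
extractFeatures <- function(image, levels = 8L, distance = 1L,
                            symmetric = TRUE,
                            which = c("averaged", "per-orientation",
                                      "all")) {
  which <- match.arg(which)
  q <- if (levels == image@levels) image else quantize(image, levels)
  angles <- c(0, 45, 90, 135)
  mats <- lapply(angles, function(a) {
    cooccurrence(q, distance = distance, angle = a, symmetric = symmetric)
  })
  avg <- averageMatrix(mats)
  if (which == "averaged") return(textureFeatures(avg))
  out <- lapply(mats, textureFeatures)
  names(out) <- paste0("a", angles)
  if (which == "all") out$avg <- textureFeatures(avg)
  out
}
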