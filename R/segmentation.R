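#' 3x3 square structuring element
#'
#' The default structuring element for the morphological clean-up stage.
#'
#' @return A 3x3 matrix of ones with its origin at the centre.
#' @export
squareSE3 <- function() matrix(1L, 3L, 3L)

#' Concentration-threshold binarization
#'
#' Global thresholding: a pixel becomes foreground (1, white) exactly when
#' its intensity strictly exceeds the threshold `t`, and background (0,
#' black) otherwise. The foreground pixel count is non-increasing in `t`.
#'
#' @param image A [GreyImage-class].
#' @param t Intensity threshold, `0 <= t < levels`.
#' @return A [BinaryMask-class] of the same shape.
#' @export
globalThreshold <- function(image, t) {
  stopifnot(is(image, "GreyImage"))
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t >= image@levels) {
    stop("'t' must lie in [0, levels - 1]")
  }
  binaryMask(image@pixels > t)
}

#' Otsu's automatic threshold
#'
#' Scans every candidate threshold `t` in `0..levels-2` and returns the one
#' maximizing the between-class variance
#' `w0(t) w1(t) (mu0(t) - mu1(t))^2` of the split into intensities
#' `<= t` and `> t`; ties break to the smallest threshold. Used as the
#' automatic choice of the concentration threshold.
#'
#' @param image A [GreyImage-class] with at least two distinct intensities.
#' @return Integer threshold suitable for [globalThreshold()].
#' @export
otsuThreshold <- function(image) {
  stopifnot(is(image, "GreyImage"))
  p <- image@pixels
  G <- image@levels
  h <- tabulate(as.vector(p) + 1L, nbins = G)
  if (sum(h > 0) < 2L) stop("degenerate input: image has a single intensity")
  n <- sum(h)
  lv <- 0:(G - 1L)
  w0 <- cumsum(h)[1:(G - 1L)]
  m0 <- cumsum(h * lv)[1:(G - 1L)]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(h * lv) - m0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  lv[which.max(bcv)]  # which.max returns the first (smallest) maximizer
}

## Shift a matrix by (dr, dc) with zero padding (values moved off the grid
## are discarded, vacated cells filled with `fill`).
.shiftMat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (rs[1L] > rs[length(rs)] || cs[1L] > cs[length(cs)]) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

.seOffsets <- function(se) {
  if (!is.matrix(se) || length(se) == 0L || !any(se != 0)) {
    stop("structuring element must be a non-empty binary matrix")
  }
  orow <- (nrow(se) + 1L) %/% 2L
  ocol <- (ncol(se) + 1L) %/% 2L
  idx <- which(se != 0, arr.ind = TRUE)
  cbind(idx[, 1L] - orow, idx[, 2L] - ocol)
}

#' Binary dilation
#'
#' `out(p) = 1` iff the reflected structuring element placed at `p` overlaps
#' any foreground pixel; the image border is handled by zero padding.
#' Dilation with an origin-containing element is extensive (the output
#' contains the input) and fills broken gaps at region edges.
#'
#' @param mask A [BinaryMask-class].
#' @param se Binary structuring element matrix with its origin at the
#'   centre; default the 3x3 square of [squareSE3()].
#' @return The dilated [BinaryMask-class].
#' @export
dilateMask <- function(mask, se = squareSE3()) {
  stopifnot(is(mask, "BinaryMask"))
  offs <- .seOffsets(se)
  m <- mask@pixels
  acc <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    ## reflected SE: offset (dr, dc) of the SE contributes the input
    ## shifted by (+dr, +dc)
    acc <- acc | .shiftMat(m, offs[i, 1L], offs[i, 2L])
  }
  binaryMask(acc)
}

#' Binary erosion
#'
#' Dual of [dilateMask()]: `out(p) = 1` iff the structuring element placed
#' at `p` fits entirely inside the foreground (zero padding, so foreground
#' touching the border erodes). For a symmetric element,
#' `erode(m) = complement(dilate(complement(m)))` exactly.
#'
#' @inheritParams dilateMask
#' @return The eroded [BinaryMask-class].
#' @export
erodeMask <- function(mask, se = squareSE3()) {
  stopifnot(is(mask, "BinaryMask"))
  offs <- .seOffsets(se)
  m <- mask@pixels
  acc <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    acc <- acc & .shiftMat(m, -offs[i, 1L], -offs[i, 2L], fill = 0L)
  }
  binaryMask(acc)
}

#' Morphological closing
#'
#' Dilation followed by erosion with the same structuring element; fills
#' small gaps while approximately preserving region size. The mask is
#' temporarily embedded in a background margin the size of the element so
#' the result equals the whole-plane closing restricted to the frame;
#' closing is therefore extensive (output contains the input) and
#' idempotent for every mask, including ones touching the border.
#'
#' @inheritParams dilateMask
#' @return The closed [BinaryMask-class].
#' @export
closeMask <- function(mask, se = squareSE3()) {
  stopifnot(is(mask, "BinaryMask"))
  r <- max(dim(se))
  m <- mask@pixels
  pad <- matrix(0L, nrow(m) + 2L * r, ncol(m) + 2L * r)
  pad[r + seq_len(nrow(m)), r + seq_len(ncol(m))] <- m
  closed <- erodeMask(dilateMask(binaryMask(pad), se), se)
  binaryMask(closed@pixels[r + seq_len(nrow(m)), r + seq_len(ncol(m)),
                           drop = FALSE])
}

## Connected-component labels of the foreground of a 0/1 matrix under
## 4-connectivity. Iterative minimum-label propagation with alternating
## forward/backward raster sweeps until a fixed point; exact, and fast for
## the blob-like masks this pipeline produces.
.labelComponents <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  lab[m != 0] <- seq_len(sum(m != 0))
  big <- sum(m != 0) + 1L
  L <- matrix(big, nr, nc)
  L[m != 0] <- lab[m != 0]
  repeat {
    old <- L
    ## propagate minima from the 4-neighbours, both sweep directions
    for (pass in 1:2) {
      up    <- rbind(rep(big, nc), L[-nr, , drop = FALSE])
      left  <- cbind(rep(big, nr), L[, -nc, drop = FALSE])
      down  <- rbind(L[-1L, , drop = FALSE], rep(big, nc))
      right <- cbind(L[, -1L, drop = FALSE], rep(big, nr))
      cand <- pmin(L, up, left, down, right)
      L[m != 0] <- cand[m != 0]
    }
    if (identical(old, L)) break
  }
  L[m == 0] <- 0L
  ## compact labels to 1..k
  u <- sort(unique(L[L > 0]))
  if (length(u)) L <- matrix(match(L, c(0L, u)) - 1L, nr, nc)
  L
}

#' Fill enclosed holes in a mask
#'
#' Background components not connected (4-connectivity) to the image border
#' are flooded to foreground; border-connected background is preserved.
#' Filling only adds pixels and is idempotent.
#'
#' @param mask A [BinaryMask-class].
#' @return The filled [BinaryMask-class].
#' @export
fillHoles <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@pixels
  bg <- 1L - m
  lab <- .labelComponents(bg)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                     lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- lab > 0 & !(lab %in% border)
  out <- m
  out[hole] <- 1L
  binaryMask(out)
}

#' Keep only the largest connected component
#'
#' @param mask A [BinaryMask-class].
#' @return A [BinaryMask-class] retaining the largest 4-connected
#'   foreground component (empty mask if the input is empty; first label
#'   wins a tie).
#' @export
largestComponent <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  lab <- .labelComponents(mask@pixels)
  if (!any(lab > 0)) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  binaryMask(lab == keep)
}

#' Map of intermixed vertical, horizontal and diagonal edges
#'
#' Computes three directional gradient-magnitude maps with 3x3 Sobel-type
#' kernels (vertical edges, horizontal edges, and the stronger of the two
#' diagonal responses), thresholds each map with Otsu's rule (a map with a
#' single magnitude value yields no edges of that type), dilates each edge
#' map with the 3x3 square, and marks the pixels where all three edge types
#' meet. Text-like regions mix all three edge directions; smooth regions
#' and isolated straight edges do not.
#'
#' @param image A [GreyImage-class], at least 3x3.
#' @return A [BinaryMask-class] of intermixed-edge regions.
#' @export
edgeMixtureMap <- function(image) {
  stopifnot(is(image, "GreyImage"))
  if (nrow(image@pixels) < 3L || ncol(image@pixels) < 3L) {
    stop("degenerate input: image must be at least 3x3")
  }
  p <- image@pixels
  sobelV <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  sobelH <- t(sobelV)
  sobelD1 <- matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3L, 3L, byrow = TRUE)
  sobelD2 <- matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3L, 3L, byrow = TRUE)
  mag <- list(
    v = abs(.conv2Reflect(p, sobelV)),
    h = abs(.conv2Reflect(p, sobelH)),
    d = pmax(abs(.conv2Reflect(p, sobelD1)), abs(.conv2Reflect(p, sobelD2)))
  )
  edge <- lapply(mag, function(g) {
    hi <- max(g)
    if (hi <= 0) return(binaryMask(matrix(0L, nrow(g), ncol(g))))
    ## quantize the magnitude map to 256 bins for the histogram scan
    qm <- floor(g * 256 / (hi + 1e-12))
    qm[qm > 255] <- 255
    q <- greyImage(qm, 256L)
    if (length(unique(as.vector(q@pixels))) < 2L) {
      return(binaryMask(matrix(0L, nrow(g), ncol(g))))
    }
    dilateMask(globalThreshold(q, otsuThreshold(q)))
  })
  binaryMask(edge$v@pixels & edge$h@pixels & edge$d@pixels)
}

#' Segment a tumour region
#'
#' The full segmentation track: binarize at the concentration threshold
#' (given, or chosen automatically by [otsuThreshold()]), clean up with a
#' morphological closing (3x3 square element), fill enclosed holes, and
#' optionally keep only the largest connected component. All intermediate
#' masks are retained in the result.
#'
#' @param image A [GreyImage-class].
#' @param threshold Intensity threshold, or `NULL` (default) for Otsu.
#' @param keepLargest Keep only the largest component (default `TRUE`).
#' @param se Structuring element for the closing.
#' @return A [SegmentationResult-class].
#' @export
segmentTumor <- function(image, threshold = NULL, keepLargest = TRUE,
                         se = squareSE3()) {
  stopifnot(is(image, "GreyImage"))
  t <- if (is.null(threshold)) otsuThreshold(image) else as.integer(threshold)
  m0 <- globalThreshold(image, t)
  m1 <- closeMask(m0, se)
  m2 <- fillHoles(m1)
  fin <- if (keepLargest) largestComponent(m2) else m2
  new("SegmentationResult",
    threshold = as.integer(t), maskThreshold = m0, maskMorph = m1,
    maskFilled = m2, final = fin
  )
}
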