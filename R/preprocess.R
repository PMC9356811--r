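## 1-D Gaussian kernel truncated at 4*sigma, normalized to sum 1.
.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Reflectively pad a matrix by r rows/cols on each side ("symmetric"
## padding: the border pixel itself is not repeated at the fold).
.padReflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(pmin(nr, pmax(1L, (r + 1L):2L)), 1:nr,
            pmin(nr, pmax(1L, (nr - 1L):(nr - r))))
  cidx <- c(pmin(nc, pmax(1L, (r + 1L):2L)), 1:nc,
            pmin(nc, pmax(1L, (nc - 1L):(nc - r))))
  m[ridx, cidx, drop = FALSE]
}

## Separable convolution with a symmetric 1-D kernel, reflective borders.
## Returns a double matrix of the input size.
.convSep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- .padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  ## rows pass
  acc <- matrix(0, nr, ncol(p))
  for (i in seq_along(k)) {
    acc <- acc + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  }
  ## cols pass
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * acc[, (i - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

## Full 2-D convolution with an arbitrary kernel (odd dims), reflective
## borders. Used for the small directional edge kernels.
.conv2Reflect <- function(m, kern) {
  rr <- (nrow(kern) - 1L) %/% 2L
  rc <- (ncol(kern) - 1L) %/% 2L
  r <- max(rr, rc)
  p <- .padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] *
        p[(r - rr + i - 1L) + seq_len(nr),
          (r - rc + j - 1L) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

## Float-valued Gaussian smoothing of a pixel matrix (no rounding); the
## building block shared by gaussianSmooth() and sharpen().
.smoothFloat <- function(p, sigma) .convSep(p, .gaussKernel(sigma))

#' Gaussian noise smoothing
#'
#' Convolves the image with a normalized 2-D Gaussian kernel (separable,
#' truncated at `4 * sigma`, reflective border handling) and rounds back to
#' the image's integer intensity range. The mean intensity is preserved up
#' to rounding, and the intensity variance never increases.
#'
#' @param image A [GreyImage-class].
#' @param sigma Gaussian standard deviation in pixels, `> 0`.
#' @return The smoothed [GreyImage-class] (same shape and levels).
#' @export
#' @seealso [sharpen()], [preprocessImage()]
gaussianSmooth <- function(image, sigma) {
  stopifnot(is(image, "GreyImage"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  out <- round(.smoothFloat(image@pixels, sigma))
  out[out < 0] <- 0
  out[out > image@levels - 1L] <- image@levels - 1L
  greyImage(out, levels = image@levels)
}

#' Contrast enhancement by unsharp masking
#'
#' High-boost sharpening used to accentuate the dissimilarity between
#' normal tissue and candidate tumour regions:
#' `out = clip(round(x + amount * (x - G_sigma(x))))` where `G_sigma` is
#' Gaussian smoothing with the internal `sigma`. `amount = 0` returns the
#' input unchanged, and a constant image is a fixed point for any amount.
#'
#' @param image A [GreyImage-class].
#' @param amount Non-negative blend weight of the high-frequency residual.
#' @param sigma Internal Gaussian width of the low-pass estimate (pixels).
#' @return The sharpened [GreyImage-class].
#' @export
sharpen <- function(image, amount, sigma = 1.0) {
  stopifnot(is(image, "GreyImage"))
  if (!is.numeric(amount) || length(amount) != 1L || amount < 0) {
    stop("'amount' must be a single non-negative number")
  }
  if (amount == 0) return(image)
  p <- image@pixels
  out <- round(p + amount * (p - .smoothFloat(p, sigma)))
  out[out < 0] <- 0
  out[out > image@levels - 1L] <- image@levels - 1L
  greyImage(out, levels = image@levels)
}

#' Run the preprocessing chain
#'
#' Applies the enabled steps in order (default smooth then sharpen), each
#' mapping a valid [GreyImage-class] to a valid [GreyImage-class].
#'
#' @param image A [GreyImage-class].
#' @param gaussianSigma Smoothing width in pixels (used when `"smooth"` is
#'   enabled).
#' @param sharpenAmount Unsharp-mask amount (used when `"sharpen"` is
#'   enabled).
#' @param steps Ordered subset of `c("smooth", "sharpen")`.
#' @return The preprocessed [GreyImage-class].
#' @export
preprocessImage <- function(image, gaussianSigma = 1.0,
                            sharpenAmount = 0.5,
                            steps = c("smooth", "sharpen")) {
  stopifnot(is(image, "GreyImage"))
  if (!all(steps %in% c("smooth", "sharpen"))) {
    stop("steps must be a subset of {smooth, sharpen}")
  }
  for (s in steps) {
    image <- switch(s,
      smooth = gaussianSmooth(image, gaussianSigma),
      sharpen = sharpen(image, sharpenAmount)
    )
  }
  image
}
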