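#' Default synthetic-texture generation settings
#'
#' The study conditions the package's evaluation runs under: 256 x 256
#' images (the working size for grey-scale MR slices; tests and the
#' bundled evaluation use 64 x 64 for speed), a smooth dark background,
#' one bright regular-texture disc for benign images, and one bright
#' irregular high-contrast region for malignant images.
#'
#' @param size Image side length in pixels (square images).
#' @param backgroundMean Background intensity level.
#' @param backgroundSigma Standard deviation of the smooth low-frequency
#'   background modulation.
#' @param blobRadiusFrac Range of the lesion radius as a fraction of the
#'   image side.
#' @param lesionMean Base intensity of the lesion interior.
#' @param benignTexturePeriod Period (pixels) of the benign lesion's
#'   sinusoidal internal texture.
#' @param benignTextureAmp Amplitude of the sinusoidal texture.
#' @param malignantContrast Amplitude of the malignant lesion's salt-like
#'   binary texture.
#' @param noiseSigma Standard deviation of the additive Gaussian pixel
#'   noise.
#' @return A named list of settings for [makeImage()] / [makeDataset()].
#' @export
syntheticSpec <- function(size = 256L, backgroundMean = 60,
                          backgroundSigma = 6,
                          blobRadiusFrac = c(0.18, 0.28),
                          lesionMean = 175,
                          benignTexturePeriod = 8,
                          benignTextureAmp = 25,
                          malignantContrast = 70,
                          noiseSigma = 5) {
  if (backgroundSigma < 0 || noiseSigma < 0 || benignTextureAmp < 0 ||
      malignantContrast < 0) {
    stop("all amplitudes and sigmas must be non-negative")
  }
  if (any(blobRadiusFrac <= 0) || any(blobRadiusFrac >= 0.5)) {
    stop("blob radii must fit inside the image")
  }
  list(
    size = as.integer(size), backgroundMean = backgroundMean,
    backgroundSigma = backgroundSigma, blobRadiusFrac = blobRadiusFrac,
    lesionMean = lesionMean, benignTexturePeriod = benignTexturePeriod,
    benignTextureAmp = benignTextureAmp,
    malignantContrast = malignantContrast, noiseSigma = noiseSigma
  )
}

## Smooth low-frequency field: heavily blurred white noise rescaled to unit
## sd (zero mean), giving the background its gentle shading.
.smoothField <- function(n, sigmaPx) {
  z <- matrix(stats::rnorm(n * n), n, n)
  s <- .smoothFloat(z, sigmaPx)
  s <- s - mean(s)
  sdv <- stats::sd(as.vector(s))
  if (sdv > 0) s / sdv else s
}

#' Generate one synthetic image with its ground-truth mask
#'
#' Emulates the three image classes the classifier separates:
#' \describe{
#'   \item{normal}{a smooth, low-variance background; empty mask.}
#'   \item{benign}{background plus one bright disc with a regular
#'     (sinusoidal) internal texture; the mask is the disc.}
#'   \item{malignant}{background plus a bright region with a randomly
#'     perturbed (irregular) boundary and high-contrast salt-like internal
#'     texture; the mask is the region.}
#' }
#' Additive Gaussian noise (`noiseSigma`) is applied everywhere and the
#' result is rounded and clipped to 0..255. Deterministic for a fixed seed.
#'
#' @param label One of `"normal"`, `"benign"`, `"malignant"`.
#' @param spec Settings from [syntheticSpec()].
#' @param seed Integer seed.
#' @return List with `image` (a [GreyImage-class]), `mask` (the
#'   ground-truth [BinaryMask-class]), `label`, and `params` (lesion
#'   radius and centre; `NULL` for normal images).
#' @export
makeImage <- function(label, spec = syntheticSpec(), seed = 1L) {
  label <- match.arg(label, .CLASS_LABELS)
  n <- spec$size
  set.seed(as.integer(seed))
  params <- NULL
  if (label != "normal") {
    ## lesion geometry is drawn first so it depends only on the seed
    r <- stats::runif(1L, spec$blobRadiusFrac[1L],
                      spec$blobRadiusFrac[2L]) * n
    cx <- stats::runif(1L, r + 2, n - r - 1)
    cy <- stats::runif(1L, r + 2, n - r - 1)
    params <- list(radius = r, center = c(cx, cy))
  }
  img <- matrix(spec$backgroundMean, n, n)
  if (spec$backgroundSigma > 0) {
    img <- img + spec$backgroundSigma * .smoothField(n, max(2, n / 16))
  }
  mask <- matrix(0L, n, n)
  if (label != "normal") {
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    dx <- rows - cx
    dy <- cols - cy
    if (label == "benign") {
      inside <- (dx^2 + dy^2) <= r^2
    } else {
      ## irregular boundary: radius modulated by random low-order harmonics
      theta <- atan2(dy, dx)
      amp <- stats::runif(3L, 0.06, 0.14)
      phase <- stats::runif(3L, 0, 2 * pi)
      rmod <- r * (1 + amp[1L] * sin(2 * theta + phase[1L]) +
                     amp[2L] * sin(3 * theta + phase[2L]) +
                     amp[3L] * sin(5 * theta + phase[3L]))
      inside <- sqrt(dx^2 + dy^2) <= rmod
    }
    mask[inside] <- 1L
    tex <- matrix(spec$lesionMean, n, n)
    if (label == "benign") {
      tex <- tex + spec$benignTextureAmp *
        sin(2 * pi * rows / spec$benignTexturePeriod) *
        sin(2 * pi * cols / spec$benignTexturePeriod)
    } else {
      salt <- matrix(stats::rbinom(n * n, 1L, 0.5), n, n)
      tex <- tex - spec$malignantContrast / 2 +
        spec$malignantContrast * salt
    }
    img[inside] <- tex[inside]
  }
  if (spec$noiseSigma > 0) {
    img <- img + stats::rnorm(n * n, sd = spec$noiseSigma)
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  list(image = greyImage(img, 256L), mask = binaryMask(mask),
       label = label, params = params)
}

#' Generate a balanced, seeded dataset
#'
#' `3 * nPerClass` items, `nPerClass` per label, with per-item seeds
#' derived deterministically from the master seed; two calls with the same
#' seed produce identical datasets.
#'
#' @param nPerClass Images per class.
#' @param spec Settings from [syntheticSpec()].
#' @param seed Master seed.
#' @return List of items as returned by [makeImage()].
#' @export
makeDataset <- function(nPerClass, spec = syntheticSpec(), seed = 1L) {
  if (nPerClass < 0) stop("'nPerClass' must be non-negative")
  if (nPerClass == 0L) return(list())
  set.seed(as.integer(seed))
  itemSeeds <- sample.int(.Machine$integer.max %/% 2L,
                          3L * nPerClass)
  labels <- rep(.CLASS_LABELS, each = nPerClass)
  lapply(seq_along(labels), function(i) {
    makeImage(labels[i], spec, seed = itemSeeds[i])
  })
}

#' Three Gaussian feature-space clusters
#'
#' Unit-test and training fuel for the classifier: three isotropic
#' unit-variance Gaussian clusters in `dims`-dimensional feature space
#' whose centres are pairwise `separation` apart (an equilateral layout in
#' the first two coordinates).
#'
#' @param nPerClass Points per class.
#' @param separation Pairwise centre distance in units of the cluster
#'   standard deviation.
#' @param dims Feature-space dimension (default 14).
#' @param seed Integer seed.
#' @return List with `x` (matrix, `3 * nPerClass` x `dims`), `labels`
#'   (character), and `centers` (3 x `dims` matrix of generating means).
#' @export
makeFeatureClusters <- function(nPerClass, separation, dims = 14L,
                                seed = 1L) {
  if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
  if (dims < 2L) stop("'dims' must be >= 2")
  set.seed(as.integer(seed))
  centers <- matrix(0, 3L, dims)
  centers[2L, 1L] <- separation
  centers[3L, 1L] <- separation / 2
  centers[3L, 2L] <- separation * sqrt(3) / 2
  n <- 3L * nPerClass
  lab <- rep(.CLASS_LABELS, each = nPerClass)
  x <- matrix(stats::rnorm(n * dims), n, dims) +
    centers[rep(1:3, each = nPerClass), ]
  colnames(x) <- if (dims == 14L) .FEATURE_NAMES else
    paste0("f", seq_len(dims))
  list(x = x, labels = lab, centers = centers)
}
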