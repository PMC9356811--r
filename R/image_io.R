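#' Read a grey-scale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit PNG or TIFF file into a [GreyImage-class] with 256
#' grey levels. Colour images are converted to grey with integer Rec. 601
#' luminance rounding, `round(0.299 R + 0.587 G + 0.114 B)` on the 0..255
#' scale; an alpha channel, if present, is ignored. 16-bit samples are
#' rescaled to 0..255 by `round(v * 255)` of the decoder's unit-range value
#' (equivalently `round(k * 255 / 65535)` for a 16-bit code `k`).
#'
#' @param path Path to an existing `.png`, `.tif` or `.tiff` file.
#' @return A [GreyImage-class] with `levels = 256`.
#' @export
#' @seealso [writeGreyImage()], [quantize()]
readGreyImage <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("'path' must be a single file path")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (need PNG or TIFF)")
  )
  if (!is.numeric(arr)) stop("could not decode image: ", path)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      ch <- round(arr[, , 1:3] * 255)
      grey <- round(0.299 * ch[, , 1L] + 0.587 * ch[, , 2L] +
                      0.114 * ch[, , 3L])
    } else {
      grey <- round(arr[, , 1L] * 255)
    }
  } else {
    grey <- round(arr * 255)
  }
  grey[grey < 0] <- 0
  grey[grey > 255] <- 255
  greyImage(grey, levels = 256L)
}

#' Write a grey-scale image or mask to PNG
#'
#' A [GreyImage-class] is written at its native intensities (scaled by
#' `levels - 1` to the 8-bit range when `levels < 256`); a
#' [BinaryMask-class] is written with background 0 and foreground 255.
#'
#' @param x A [GreyImage-class] or [BinaryMask-class].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
writeGreyImage <- function(x, path) {
  if (is(x, "BinaryMask")) {
    m <- x@pixels * 1.0
  } else if (is(x, "GreyImage")) {
    m <- if (x@levels == 256L) x@pixels / 255 else
      round(x@pixels * 255 / (x@levels - 1L)) / 255
  } else {
    stop("'x' must be a GreyImage or BinaryMask")
  }
  png::writePNG(m, target = path)
  invisible(path)
}

#' Quantize an image to a smaller number of grey levels
#'
#' By default intensities are binned uniformly over the full representable
#' range `0..image levels - 1` (so a mid-grey pixel maps to the same bin in
#' every image and features stay comparable across images): intensity `k`
#' maps to `floor(k * levels / G_in)`. With `stretch = TRUE` the observed
#' min--max range of this image is stretched over the output bins instead.
#' Both mappings are monotone non-decreasing, and quantization at fixed
#' `levels` is idempotent.
#'
#' @param image A [GreyImage-class].
#' @param levels Target number of grey levels, `2 <= levels <=` input
#'   levels.
#' @param stretch Use min--max stretching instead of the full-range binning.
#' @return A [GreyImage-class] with `levels` grey levels.
#' @export
#' @examples
#' img <- greyImage(matrix(0:255, 16, 16), levels = 256)
#' range(pixels(quantize(img, 8)))
quantize <- function(image, levels, stretch = FALSE) {
  stopifnot(is(image, "GreyImage"))
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("'levels' must be an integer >= 2")
  if (levels > image@levels) {
    stop("'levels' must not exceed the image's grey-level count")
  }
  p <- image@pixels
  if (stretch) {
    lo <- min(p); hi <- max(p)
    if (hi == lo) {
      q <- matrix(0L, nrow(p), ncol(p))
    } else {
      q <- floor((p - lo) * levels / (hi - lo + 1L))
    }
  } else {
    q <- floor(p * levels / image@levels)
  }
  q[q > levels - 1L] <- levels - 1L
  greyImage(q, levels = levels)
}

#' Write a feature table to CSV
#'
#' Writes one row per image with columns `image_id`, `label`, then the 14
#' feature names of [textureFeatureNames()] (optionally prefixed, e.g.
#' `avg_contrast`). Values are printed with 17 significant digits so that
#' [readFeatureTable()] reproduces them exactly.
#'
#' @param rows A list; each element a list with components `id`, `label` and
#'   `features` (a [TextureFeatures-class] or named numeric vector in
#'   feature order).
#' @param path Output CSV path.
#' @param prefix Optional prefix prepended to every feature column name.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(rows, path, prefix = "") {
  header <- c("image_id", "label", paste0(prefix, .FEATURE_NAMES))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (r in rows) {
    v <- r$features
    if (is(v, "TextureFeatures")) v <- v@values
    if (length(v) != length(.FEATURE_NAMES)) {
      stop("every feature vector must have exactly 14 values")
    }
    writeLines(paste(
      c(as.character(r$id), as.character(r$label), sprintf("%.17g", v)),
      collapse = ","
    ), con)
  }
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return A data.frame with `image_id`, `label` and 14 numeric feature
#'   columns.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (ncol(df) != 2L + length(.FEATURE_NAMES)) {
    stop("feature table must have 2 + 14 columns")
  }
  df
}
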