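# Raster conventions: images are numeric H x W (grayscale) or H x W x C
# arrays, row = y, col = x, intensities on the 8-bit [0, 255] scale.
# EBImage stores transposed (x, y[, c]) planes in [0, 1]; the converters
# below keep that mapping in one place.

#' Validate a raster image array
#'
#' Checks the in-memory image contract: a numeric H x W matrix or
#' H x W x C array (C in {1, 3}) with finite intensities in [0, 255].
#'
#' @param image matrix or 3-d array.
#' @param minSize minimum height/width; the segmentation pipeline requires
#'   64 so that the sampling patches fit.
#' @return The image, invisibly, after validation.
#' @export
assertRaster <- function(image, minSize = 1L) {
  if (!is.numeric(image) || !(length(dim(image)) %in% c(2L, 3L)))
    stop("image must be a numeric H x W matrix or H x W x C array")
  if (length(dim(image)) == 3L && !dim(image)[3] %in% c(1L, 3L))
    stop("image must have 1 or 3 channels")
  if (any(!is.finite(image)))
    stop("image intensities must all be finite")
  if (min(image) < 0 || max(image) > 255)
    stop("image intensities must lie within [0, 255]")
  if (nrow(image) < minSize || ncol(image) < minSize)
    stop(sprintf("image must be at least %dx%d", minSize, minSize))
  invisible(image)
}

#' Read an image file as a raster array
#'
#' Reads PNG/TIFF/JPEG through EBImage and returns an H x W (grayscale)
#' matrix or H x W x 3 array on the [0, 255] intensity scale.
#'
#' @param path image file path.
#' @return Numeric matrix or array, intensities in [0, 255].
#' @export
readRasterImage <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) {
    out <- t(dat) * 255
  } else {
    nc <- dim(dat)[3]
    if (nc >= 3L) {
      out <- array(0, dim = c(dim(dat)[2], dim(dat)[1], 3L))
      for (k in 1:3) out[, , k] <- t(dat[, , k]) * 255
    } else {
      out <- t(dat[, , 1]) * 255
    }
  }
  out
}

#' Write a grayscale field or color image
#'
#' @param image H x W matrix or H x W x 3 array in [0, 255].
#' @param path output path; format chosen from the file extension
#'   (png/tiff/jpeg).
#' @return \code{path}, invisibly.
#' @export
writeRasterImage <- function(image, path) {
  image <- pmin(pmax(image, 0), 255) / 255
  if (length(dim(image)) == 3L) {
    dat <- array(0, dim = c(dim(image)[2], dim(image)[1], dim(image)[3]))
    for (k in seq_len(dim(image)[3])) dat[, , k] <- t(image[, , k])
    img <- EBImage::Image(dat, colormode = "Color")
  } else {
    img <- EBImage::Image(t(image), colormode = "Grayscale")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask H x W matrix of {0, 1}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskImage <- function(mask, path) {
  writeRasterImage(matrix(as.numeric(mask != 0) * 255, nrow(mask)), path)
}

#' Read a binary mask from an image file
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path image file path.
#' @return Integer H x W matrix of {0, 1}.
#' @export
readMaskImage <- function(path) {
  img <- readRasterImage(path)
  if (length(dim(img)) == 3L) img <- toGrayscale(img)
  m <- matrix(as.integer(img > 127.5), nrow(img))
  m
}

#' Write a real-valued field as 32-bit float TIFF
#'
#' Used to export intermediate fields (edge maps, probability maps) at
#' full precision.
#'
#' @param field H x W numeric matrix.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeFloatTiff <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write float TIFF files")
  tiff::writeTIFF(field, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Collapse a color image to grayscale
#'
#' Uses the unweighted mean of the channels.
#'
#' @param image H x W matrix (returned unchanged) or H x W x C array.
#' @return H x W numeric matrix.
#' @export
toGrayscale <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  out <- image[, , 1]
  nc <- dim(image)[3]
  if (nc > 1L) for (k in 2:nc) out <- out + image[, , k]
  out / nc
}
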