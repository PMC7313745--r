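#' Create a GrayImage
#'
#' @param pixels numeric or integer matrix of intensities in \[0, 255\];
#'   non-integer values are rejected (quantization is the caller's choice).
#' @param pixelPitchUm physical pixel size in micrometers (default 40).
#' @return a [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(230L, 64, 64))
#' dim(img)
#' @export
grayImage <- function(pixels, pixelPitchUm = 40) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (is.double(pixels)) {
    if (any(pixels != floor(pixels), na.rm = TRUE))
      stop("pixel intensities must be whole numbers in [0, 255]")
    storage.mode(pixels) <- "integer"
  }
  new("GrayImage", pixels = pixels, pixelPitchUm = as.numeric(pixelPitchUm))
}

#' @describeIn grayImage pixel matrix accessor
#' @param x,object a `GrayImage`
#' @export
pixels <- function(x) x@pixels

#' @describeIn grayImage physical pixel pitch in micrometers
#' @export
pixelPitch <- function(x) x@pixelPitchUm

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage: %d x %d px, 8-bit, %.1f um/px (%.1f x %.1f mm)\n",
    d[1], d[2], object@pixelPitchUm,
    d[1] * object@pixelPitchUm / 1000, d[2] * object@pixelPitchUm / 1000))
  if (length(object@pixels))
    cat(sprintf("  intensity range: [%d, %d]\n",
      min(object@pixels), max(object@pixels)))
})

#' Read an 8-bit grayscale plate image
#'
#' Reads a PNG or TIFF file into a [GrayImage-class]. Grayscale 8-bit input
#' round-trips bit-identically. Higher bit depths are accepted and linearly
#' rescaled to 8 bits with a warning; color images are rejected (use a
#' grayscale camera or convert upstream, counting needs intensity only).
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param pixelPitchUm physical pixel size of the recording, micrometers.
#' @return a [GrayImage-class].
#' @seealso [writeGrayImage()]
#' @export
readGrayImage <- function(path, pixelPitchUm = 40) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF): ", path))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L)
      stop("color image not supported: ", path,
           " (record in grayscale; colony counting uses intensity only)")
    warning("dropping alpha channel of ", path)
    arr <- arr[, , 1L]
  }
  v <- arr * 255
  if (any(abs(v - round(v)) > 1e-9)) {
    warning("input is not 8-bit; linearly rescaling intensities to [0, 255]: ",
            path)
  }
  grayImage(matrix(as.integer(round(v)), nrow(arr), ncol(arr)),
            pixelPitchUm = pixelPitchUm)
}

#' Write a GrayImage as an 8-bit grayscale PNG or TIFF
#'
#' @param img a [GrayImage-class].
#' @param path destination file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  stopifnot(is(img, "GrayImage"))
  v <- img@pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, target = path),
    tif = ,
    tiff = tiff::writeTIFF(v, where = path, bits.per.sample = 8L),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)"))
  invisible(path)
}

# round-half-up to integer; the one rounding rule used by every linear
# intensity rescaling in the package
roundHalfUp <- function(x) floor(x + 0.5)
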