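#' Rolling-ball background subtraction
#'
#' Removes smooth background variation at scales larger than a ball of the
#' given radius, the classical first step before spot counting: the
#' background surface is estimated by grayscale closing (light background)
#' or opening (dark background) with a flat disc structuring element of
#' radius `radiusPx`, conceptually rolling the ball across the intensity
#' surface. With a light background the output is `img - background + 255`,
#' so flat or smoothly varying regions map to full white (255) while dark
#' objects of diameter up to `2 * radiusPx` keep their depth below the
#' (now white) surround. Objects larger than the ball are treated as
#' background and substantially lightened, so the radius must exceed the
#' largest colony to be detected (50 px = 4 mm at 40 um/px).
#'
#' Borders are handled by edge replication of the input before both
#' morphological passes, which keeps gradients flattenable up to the image
#' edge.
#'
#' @param img a [GrayImage-class].
#' @param radiusPx ball radius in pixels (>= 1, at most the smaller image
#'   dimension).
#' @param lightBackground `TRUE` for dark objects on a bright background.
#' @return a [GrayImage-class] of identical dimensions.
#' @examples
#' flat <- grayImage(matrix(180L, 32, 32))
#' all(pixels(subtractBackground(flat, 15)) == 255L)
#' @export
setGeneric("subtractBackground",
  function(img, radiusPx, lightBackground = TRUE)
    standardGeneric("subtractBackground"))

#' @rdname subtractBackground
setMethod("subtractBackground", "GrayImage",
  function(img, radiusPx, lightBackground = TRUE) {
    r <- checkRadius(radiusPx)
    if (r > min(dim(img@pixels)))
      stop("ball radius (", r, ") exceeds the smaller image dimension (",
           min(dim(img@pixels)), ")")
    px <- img@pixels
    if (lightBackground) {
      bg <- .cppMorphDisc(px, r, 2L)   # closing: background from above
      out <- px - bg + 255L
    } else {
      bg <- .cppMorphDisc(px, r, 3L)   # opening: background from below
      out <- px - bg
    }
    out[out < 0L] <- 0L
    out[out > 255L] <- 255L
    initialize(img, pixels = out)
  })

#' Automatic contrast expansion
#'
#' Linearly spreads the gray values across the full dynamic range: the
#' intensities at the `saturationFraction` lower and upper percentiles
#' (computed over `roi` if given, else the whole image) map to 0 and 255,
#' values beyond clamp. Together with background subtraction this equalizes
#' images that initially differed in brightness; the output depends only on
#' the input histogram and the fraction. Restricting the statistics to the
#' ROI keeps ink marks or text outside the countable area from skewing the
#' stretch.
#'
#' Degenerate input is returned unchanged: a constant region, and more
#' generally a region whose percentile range does not exceed `minRange`.
#' Contrast expansion presumes that the gray values represent either
#' remaining background or objects to be detected; when the whole range is
#' within the sensor-noise floor there is nothing to detect and stretching
#' would only amplify noise into spurious structure. The default floor is
#' one eighth of the dynamic range (32 gray levels), far above the noise
#' spread of a flat region yet far below the depth of any real colony.
#'
#' @param img a [GrayImage-class].
#' @param saturationFraction fraction of pixels saturated per tail, in
#'   \[0, 0.5); default 0.0035.
#' @param roi optional [Roi-class]; percentiles are computed over its
#'   member pixels, the mapping is applied to the whole image.
#' @param minRange smallest percentile range (gray levels) that is
#'   stretched; smaller ranges are treated as object-free and left
#'   unchanged. Set to 1 to always stretch.
#' @return a [GrayImage-class] of identical dimensions.
#' @export
setGeneric("autoContrast",
  function(img, saturationFraction = 0.0035, roi = NULL, minRange = 32L)
    standardGeneric("autoContrast"))

#' @rdname autoContrast
setMethod("autoContrast", "GrayImage",
  function(img, saturationFraction = 0.0035, roi = NULL, minRange = 32L) {
    if (saturationFraction < 0 || saturationFraction >= 0.5)
      stop("saturation fraction must lie in [0, 0.5)")
    px <- img@pixels
    vals <- if (is.null(roi)) px else px[roiMask(roi, dim(px))]
    if (!length(vals)) stop("contrast statistics require a non-empty region")
    s <- sort.int(vals, method = "radix")
    nsat <- floor(saturationFraction * length(s))
    lo <- s[nsat + 1L]
    hi <- s[length(s) - nsat]
    if (hi - lo < minRange) return(img)  # degenerate range: identity
    # multiply before dividing so exact half-values round deterministically
    out <- roundHalfUp((px - lo) * 255 / (hi - lo))
    out[out < 0] <- 0
    out[out > 255] <- 255
    initialize(img, pixels = matrix(as.integer(out), nrow(px), ncol(px)))
  })

#' Disc median filter
#'
#' Replaces each pixel by the median intensity within a disc of the given
#' radius, the noise-removal step of the pipeline: suppresses sensor noise
#' far more effectively than linear smoothing while preserving edges, and
#' eliminates isolated features smaller than the disc (which intentionally
#' excludes micro-colonies below the minimum size one would count by eye;
#' 6 px corresponds to ~0.25 mm at 40 um/px). Borders use edge replication
#' so no artificial dark rim is created.
#'
#' @param img a [GrayImage-class].
#' @param radiusPx disc radius in pixels (>= 1).
#' @return a [GrayImage-class] of identical dimensions.
#' @export
setGeneric("medianFilter",
  function(img, radiusPx) standardGeneric("medianFilter"))

#' @rdname medianFilter
setMethod("medianFilter", "GrayImage", function(img, radiusPx) {
  r <- checkRadius(radiusPx)
  initialize(img, pixels = .cppMedianDisc(img@pixels, r))
})

#' Saturating brightness lift
#'
#' Adds a constant to every pixel, clamping at white: `min(v + delta, 255)`.
#' Applied after contrast expansion and median filtering, this lifts the
#' residual low-contrast background above the 8-bit maximum so only genuine
#' colony interiors keep grayscale structure below white; 135 is the
#' reference setting.
#'
#' @param img a [GrayImage-class].
#' @param delta integer in \[0, 255\].
#' @return a [GrayImage-class] of identical dimensions.
#' @export
setGeneric("liftBrightness",
  function(img, delta) standardGeneric("liftBrightness"))

#' @rdname liftBrightness
setMethod("liftBrightness", "GrayImage", function(img, delta) {
  delta <- as.integer(delta)
  if (length(delta) != 1L || is.na(delta) || delta < 0L || delta > 255L)
    stop("'delta' must be a single integer in [0, 255]")
  out <- img@pixels + delta
  out[out > 255L] <- 255L
  initialize(img, pixels = out)
})

#' Detect colony centers as prominent regional minima
#'
#' Counts the local brightness minima of the processed image: each colony
#' center is the darkest spot of its colony, so one point is returned per
#' regional minimum (8-connected equal-intensity plateau strictly darker
#' than all its in-mask neighbors) whose prominence reaches
#' `minProminence`. Prominence is the intensity depth between the minimum
#' and the lowest saddle connecting it to a deeper minimum (for the
#' deepest minimum of a region, its depth below the lifted white
#' background, 255). Thresholding prominence separates colony centers from
#' residual noise, and clustered colonies are still resolved into multiple
#' centers as long as each keeps its own darkest core. Pixels at exactly
#' 255 are lifted background and never minima; a flat plateau yields
#' exactly one point at its centroid pixel (ties to smallest row, then
#' column).
#'
#' @param img a [GrayImage-class] (normally the pipeline's lifted image).
#' @param minProminence integer >= 1.
#' @param roi optional [Roi-class] restricting the search; `NULL` searches
#'   the whole image.
#' @return data.frame with integer columns `row`, `col`, `prominence`
#'   (1-based pixel coordinates), ordered by row then column.
#' @export
setGeneric("findLocalMinima",
  function(img, minProminence, roi = NULL) standardGeneric("findLocalMinima"))

#' @rdname findLocalMinima
setMethod("findLocalMinima", "GrayImage",
  function(img, minProminence, roi = NULL) {
    minProminence <- as.integer(minProminence)
    if (length(minProminence) != 1L || is.na(minProminence) ||
        minProminence < 1L)
      stop("'minProminence' must be a single integer >= 1")
    mask <- if (is.null(roi)) {
      matrix(TRUE, nrow(img@pixels), ncol(img@pixels))
    } else {
      roiMask(roi, dim(img@pixels))
    }
    hits <- .cppFindMinima(img@pixels, mask, minProminence)
    as.data.frame(hits)
  })

# shared radius check for neighborhood operators
checkRadius <- function(radiusPx) {
  r <- as.integer(radiusPx)
  if (length(r) != 1L || is.na(r) || r < 1L)
    stop("radius must be a single integer >= 1")
  r
}

# mask of an Roi, validated against the image dimensions
roiMask <- function(roi, dims) {
  stopifnot(is(roi, "Roi"))
  if (!identical(dim(roi@mask), as.integer(dims)))
    stop("ROI mask dimensions (", paste(dim(roi@mask), collapse = "x"),
         ") do not match the image (", paste(dims, collapse = "x"), ")")
  roi@mask
}
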