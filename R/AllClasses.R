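#' GrayImage: an 8-bit grayscale raster with physical pixel pitch
#'
#' The sole pixel currency of the enumeration pipeline: a matrix of integer
#' intensities in \[0, 255\] (dark colonies on a bright background) together
#' with the physical size of one pixel in micrometers. Every pipeline
#' operator maps a `GrayImage` to a `GrayImage` of identical dimensions.
#'
#' @slot pixels integer matrix, values in \[0, 255\]; rows index image rows.
#' @slot pixelPitchUm physical edge length of one pixel in micrometers
#'   (default 40, i.e. a 2 mm colony spans 50 pixels).
#' @seealso [grayImage()], [readGrayImage()], [writeGrayImage()]
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", pixelPitchUm = "numeric"),
  prototype(pixels = matrix(0L, 0, 0), pixelPitchUm = 40))

setValidity("GrayImage", function(object) {
  px <- object@pixels
  if (!is.integer(px)) return("'pixels' must be an integer matrix")
  if (length(px) && (anyNA(px) || min(px) < 0L || max(px) > 255L))
    return("pixel intensities must be integers in [0, 255]")
  if (length(object@pixelPitchUm) != 1L || !is.finite(object@pixelPitchUm) ||
      object@pixelPitchUm <= 0)
    return("'pixelPitchUm' must be a single positive number")
  TRUE
})

#' PipelineParams: operator parameters of the enumeration pipeline
#'
#' Defaults reproduce the reference configuration: a rolling-ball radius of
#' 50 px (removes background structure larger than 4 mm at 40 um/px), a
#' median working radius of 6 px (~0.25 mm, the smallest object retained),
#' a brightness lift of 135 gray levels (pushes residual background above
#' white), a minimum prominence of 10 gray levels for minima detection, and
#' 0.35% per-tail saturation for automatic contrast expansion.
#'
#' @slot rollingBallRadiusPx integer, background-subtraction ball radius.
#' @slot medianRadiusPx integer, disc radius of the median filter.
#' @slot brightnessLift integer in \[0, 255\], added saturating at white.
#' @slot minProminence integer >= 1, minimum depth of a counted minimum
#'   below its lowest connecting saddle (noise tolerance).
#' @slot contrastSaturationFraction fraction of pixels saturated per tail
#'   by the contrast stretch, in \[0, 0.5).
#' @slot lightBackground logical; `TRUE` for dark objects on a bright
#'   background (the transmissive-illumination case).
#' @seealso [pipelineParams()], [runPipeline()]
#' @exportClass PipelineParams
setClass("PipelineParams",
  representation(rollingBallRadiusPx = "integer", medianRadiusPx = "integer",
    brightnessLift = "integer", minProminence = "integer",
    contrastSaturationFraction = "numeric", lightBackground = "logical"))

setValidity("PipelineParams", function(object) {
  p <- object
  if (p@rollingBallRadiusPx < 1L) return("rolling-ball radius must be >= 1")
  if (p@medianRadiusPx < 1L) return("median radius must be >= 1")
  if (p@rollingBallRadiusPx <= p@medianRadiusPx)
    return("background scale (ball radius) must exceed object scale (median radius)")
  if (p@brightnessLift < 0L || p@brightnessLift > 255L)
    return("brightness lift must lie in [0, 255]")
  if (p@minProminence < 1L) return("minimum prominence must be >= 1")
  if (p@contrastSaturationFraction < 0 || p@contrastSaturationFraction >= 0.5)
    return("contrast saturation fraction must lie in [0, 0.5)")
  TRUE
})

#' PlateLayout: geometry of the countable area of a Petri dish
#'
#' Describes the dish position in the image and how the countable region is
#' carved out of it: either the full inset disc, or six wedge segments
#' (dilution plates carry two segments for each of three dilution levels).
#' Regions end a few millimeters short of the dish rim, which keeps rim
#' colony clusters and the thicker broth layer near the wall out of the
#' counted area.
#'
#' @slot centerRow,centerCol dish center in pixel coordinates (1-based).
#' @slot dishRadiusPx dish radius in pixels.
#' @slot nSegments 1 (whole plate) or 6 (segmented plate).
#' @slot rimInsetMm radial inset of the countable region from the rim, mm.
#' @slot segmentGapDeg angular gap between adjacent wedges, degrees; models
#'   the colony-free border strips drawn on segmented dishes.
#' @slot rotationDeg orientation of the first segment boundary, degrees
#'   counter-clockwise.
#' @slot pixelPitchUm micrometers per pixel (used to convert the inset).
#' @slot imageNrow,imageNcol dimensions of the image the layout refers to.
#' @seealso [plateLayout()], [makeFullPlateRoi()], [makeSegmentRois()]
#' @exportClass PlateLayout
setClass("PlateLayout",
  representation(centerRow = "numeric", centerCol = "numeric",
    dishRadiusPx = "numeric", nSegments = "integer", rimInsetMm = "numeric",
    segmentGapDeg = "numeric", rotationDeg = "numeric",
    pixelPitchUm = "numeric", imageNrow = "integer", imageNcol = "integer"))

setValidity("PlateLayout", function(object) {
  if (!(object@nSegments %in% c(1L, 6L))) return("nSegments must be 1 or 6")
  if (object@dishRadiusPx <= 0) return("dish radius must be positive")
  if (object@rimInsetMm < 0) return("rim inset must be >= 0")
  if (object@segmentGapDeg < 0) return("segment gap must be >= 0")
  if (object@nSegments == 6L && object@segmentGapDeg >= 60)
    return("segment gap must be smaller than the 60 degree wedge span")
  if (effectiveRoiRadius(object) <= 0)
    return("rim inset leaves no countable area (inset >= dish radius)")
  if (object@imageNrow < 1L || object@imageNcol < 1L)
    return("image dimensions must be positive")
  TRUE
})

#' Roi: a countable region of interest
#'
#' Pixel-membership mask over the image grid plus a label. ROIs are
#' rasterized once per layout so membership tests during counting are
#' constant-time lookups.
#'
#' @slot mask logical matrix with the image's dimensions.
#' @slot label region label, e.g. `"full_plate"` or `"segment_3"`.
#' @exportClass Roi
setClass("Roi", representation(mask = "matrix", label = "character"))

setValidity("Roi", function(object) {
  if (!is.logical(object@mask)) return("'mask' must be a logical matrix")
  if (anyNA(object@mask)) return("'mask' must not contain NA")
  if (length(object@label) != 1L) return("'label' must be a single string")
  TRUE
})

#' CountResult: enumeration result for one plate image
#'
#' @slot perRoi data.frame with one row per ROI: `label`, `count`,
#'   `fullPlateEquivalent` (count scaled by the number of segments so that
#'   segment counts compare to whole-plate counts), and the text anchor
#'   position used by [annotateImage()].
#' @slot centers list (one element per ROI) of data.frames with columns
#'   `row`, `col`, `prominence`: the detected colony center pixels.
#' @slot totalCount sum of per-ROI counts.
#' @slot processedImages list of `GrayImage`s as seen by the minima
#'   detector (one per ROI; they differ only in the ROI-restricted
#'   contrast statistics).
#' @slot paramsUsed the `PipelineParams` the counts were produced with.
#' @slot layout the `PlateLayout` that defined the ROIs.
#' @seealso [enumeratePlate()]
#' @exportClass CountResult
setClass("CountResult",
  representation(perRoi = "data.frame", centers = "list",
    totalCount = "integer", processedImages = "list",
    paramsUsed = "PipelineParams", layout = "PlateLayout"))

setValidity("CountResult", function(object) {
  if (sum(object@perRoi$count) != object@totalCount)
    return("totalCount must equal the sum of per-ROI counts")
  nc <- vapply(object@centers, nrow, 0L)
  if (!identical(unname(nc), unname(object@perRoi$count)))
    return("each ROI's count must equal its number of centers")
  TRUE
})

#' SyntheticPlateSpec: recipe for a synthetic plate image
#'
#' Describes the study conditions the generator emulates: dark circular
#' colonies of 0.5-4 mm on a bright background (~230 of 255) whose
#' brightness varies smoothly across the plate (broth-layer thickness),
#' plus additive sensor noise, imaged at ~40 um/pixel. Colony darkness
#' profiles are near-flat opaque cores with a steep smooth rim
#' (`darkness * (1 - rho^profileExponent)`), combined across overlapping
#' colonies by per-pixel maximum so that confluent colonies keep one
#' darkest spot each.
#'
#' @slot layout `PlateLayout` giving the plate geometry and the ROIs the
#'   colonies are placed in.
#' @slot nColonies integer; either one total (full plates) or one count per
#'   segment.
#' @slot diameterRangeMm colony diameters drawn uniformly from this range.
#' @slot darknessRange central intensity drop below the local background,
#'   drawn uniformly; near-opaque colonies under backlight.
#' @slot backgroundLevel base background intensity.
#' @slot gradientAmplitude amplitude of the low-order polynomial background
#'   field emulating variable broth-layer thickness (gray levels).
#' @slot noiseSigma SD of additive Gaussian sensor noise (gray levels).
#' @slot minSeparationMm minimum distance between colony centers; the
#'   default (twice the largest diameter) generates well-separated plates,
#'   smaller values create confluence.
#' @slot profileExponent exponent of the radial darkness profile.
#' @slot seed RNG seed; generation is a pure function of (spec, seed).
#' @seealso [syntheticPlateSpec()], [generatePlate()]
#' @exportClass SyntheticPlateSpec
setClass("SyntheticPlateSpec",
  representation(layout = "PlateLayout", nColonies = "integer",
    diameterRangeMm = "numeric", darknessRange = "numeric",
    backgroundLevel = "numeric", gradientAmplitude = "numeric",
    noiseSigma = "numeric", minSeparationMm = "numeric",
    profileExponent = "numeric", seed = "integer"))

setValidity("SyntheticPlateSpec", function(object) {
  s <- object
  nRoi <- if (s@layout@nSegments == 1L) 1L else 6L
  if (!(length(s@nColonies) %in% c(1L, nRoi)))
    return("nColonies must be one total or one count per segment")
  if (any(s@nColonies < 0L)) return("colony counts must be >= 0")
  if (length(s@diameterRangeMm) != 2L || any(s@diameterRangeMm <= 0) ||
      diff(s@diameterRangeMm) < 0)
    return("diameterRangeMm must be an increasing positive pair")
  if (length(s@darknessRange) != 2L || any(s@darknessRange < 1) ||
      diff(s@darknessRange) < 0 || max(s@darknessRange) > 255)
    return("darknessRange must be an increasing pair in [1, 255]")
  if (s@backgroundLevel < 0 || s@backgroundLevel > 255)
    return("backgroundLevel must lie in [0, 255]")
  if (s@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (s@minSeparationMm < 0) return("minSeparationMm must be >= 0")
  if (s@profileExponent <= 0) return("profileExponent must be positive")
  TRUE
})

#' GroundTruth: placed colony centers of a synthetic plate
#'
#' @slot centers data.frame with columns `label`, `row`, `col`,
#'   `radiusPx`, `darkness`: one row per placed colony.
#' @slot nPerRoi named integer vector of colonies per ROI.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(centers = "data.frame", nPerRoi = "integer"))

setValidity("GroundTruth", function(object) {
  if (sum(object@nPerRoi) != nrow(object@centers))
    return("per-ROI counts must sum to the number of placed colonies")
  TRUE
})

#' RegressionResult: slope of an error-weighted fit through the origin
#'
#' Result of the effective-variance (errors-in-variables) regression
#' `y = b * x` with relative errors `cvX` on x and `cvY` on y, used to
#' compare two enumeration methods that must agree at zero colonies.
#'
#' @slot slope fitted proportionality constant.
#' @slot se standard error of the slope (chi-square curvature).
#' @slot ci95Low,ci95High 95% confidence bounds (slope +- 1.96 se).
#' @slot cvX,cvY assigned relative errors.
#' @slot nPoints number of samples.
#' @slot chisqMin minimized effective-variance chi-square.
#' @seealso [originRegression()], [correctionFactor()]
#' @exportClass RegressionResult
setClass("RegressionResult",
  representation(slope = "numeric", se = "numeric", ci95Low = "numeric",
    ci95High = "numeric", cvX = "numeric", cvY = "numeric",
    nPoints = "integer", chisqMin = "numeric"))

setValidity("RegressionResult", function(object) {
  if (!(object@ci95Low <= object@slope && object@slope <= object@ci95High))
    return("confidence interval must contain the slope")
  TRUE
})
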