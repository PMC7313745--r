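#' Create pipeline parameters
#'
#' All defaults reproduce the reference enumeration configuration; see
#' [PipelineParams-class] for the meaning and units of each value.
#'
#' @param rollingBallRadiusPx background ball radius, default 50 px (4 mm
#'   maximum object diameter at 40 um/px).
#' @param medianRadiusPx median disc radius, default 6 px (~0.25 mm).
#' @param brightnessLift saturating lift, default 135.
#' @param minProminence minima noise tolerance, default 10 gray levels.
#' @param contrastSaturationFraction per-tail saturation, default 0.0035.
#' @param lightBackground dark colonies on bright background, default TRUE.
#' @return a [PipelineParams-class].
#' @examples
#' pipelineParams()
#' @export
pipelineParams <- function(rollingBallRadiusPx = 50, medianRadiusPx = 6,
                           brightnessLift = 135, minProminence = 10,
                           contrastSaturationFraction = 0.0035,
                           lightBackground = TRUE) {
  new("PipelineParams",
    rollingBallRadiusPx = as.integer(rollingBallRadiusPx),
    medianRadiusPx = as.integer(medianRadiusPx),
    brightnessLift = as.integer(brightnessLift),
    minProminence = as.integer(minProminence),
    contrastSaturationFraction = as.numeric(contrastSaturationFraction),
    lightBackground = as.logical(lightBackground))
}

setMethod("show", "PipelineParams", function(object) {
  cat(sprintf(paste0(
    "PipelineParams: ball=%d px, median=%d px, lift=%d, prominence=%d,\n",
    "  contrast saturation=%.4f/tail, %s background\n"),
    object@rollingBallRadiusPx, object@medianRadiusPx,
    object@brightnessLift, object@minProminence,
    object@contrastSaturationFraction,
    if (object@lightBackground) "light" else "dark"))
})

#' Run the five-stage enumeration pipeline on one region of interest
#'
#' Applies, in order: background subtraction (rolling ball), automatic
#' contrast expansion (percentile statistics over the ROI only, so marks
#' outside the countable area cannot skew the stretch), disc median
#' filtering, the saturating brightness lift, and prominence-thresholded
#' regional-minimum detection restricted to the ROI. Pixel-level operators
#' run on the full image; only the contrast statistics and the minima
#' search are ROI-restricted. Identical inputs give bit-identical results.
#'
#' @param img a [GrayImage-class].
#' @param roi an [Roi-class], or `NULL` for the whole image.
#' @param params a [PipelineParams-class].
#' @return list with `image` (the processed, lifted [GrayImage-class]) and
#'   `centers` (data.frame `row`, `col`, `prominence`).
#' @seealso [enumeratePlate()] for whole plates with layouts.
#' @export
runPipeline <- function(img, roi = NULL, params = pipelineParams()) {
  stopifnot(is(img, "GrayImage"), is(params, "PipelineParams"))
  validObject(params)
  x <- subtractBackground(img, params@rollingBallRadiusPx,
                          params@lightBackground)
  x <- autoContrast(x, params@contrastSaturationFraction, roi = roi)
  x <- medianFilter(x, params@medianRadiusPx)
  x <- liftBrightness(x, params@brightnessLift)
  centers <- findLocalMinima(x, params@minProminence, roi = roi)
  list(image = x, centers = centers)
}

#' Enumerate a plate image
#'
#' Runs [runPipeline()] for each region of the layout (the full inset disc,
#' or six wedge segments) and assembles a [CountResult-class]: per-ROI
#' counts with detected center coordinates, the total, and full-plate
#' equivalents (segment counts scaled by 6 so different dilutions compare
#' to whole-plate counts). All parameters are predefined, so re-running on
#' the same image is bit-identical.
#'
#' @param img a [GrayImage-class].
#' @param layout a [PlateLayout-class] consistent with the image size.
#' @param params a [PipelineParams-class].
#' @return a [CountResult-class].
#' @export
enumeratePlate <- function(img, layout, params = pipelineParams()) {
  stopifnot(is(img, "GrayImage"), is(layout, "PlateLayout"))
  if (!identical(dim(img@pixels),
                 c(layout@imageNrow, layout@imageNcol)))
    stop("layout image dimensions (", layout@imageNrow, "x",
         layout@imageNcol, ") do not match the image (",
         paste(dim(img@pixels), collapse = "x"), ")")
  rois <- if (layout@nSegments == 1L) list(makeFullPlateRoi(layout))
          else makeSegmentRois(layout)
  centers <- vector("list", length(rois))
  imgs <- vector("list", length(rois))
  rowsOut <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    res <- runPipeline(img, rois[[i]], params)
    centers[[i]] <- res$centers
    imgs[[i]] <- res$image
    anchor <- .roiAnchor(rois[[i]])
    rowsOut[[i]] <- data.frame(label = rois[[i]]@label,
      count = nrow(res$centers),
      fullPlateEquivalent = scaleSegmentCount(nrow(res$centers),
                                              layout@nSegments),
      anchorRow = anchor[1], anchorCol = anchor[2],
      stringsAsFactors = FALSE)
  }
  perRoi <- do.call(rbind, rowsOut)
  names(centers) <- names(imgs) <- perRoi$label
  new("CountResult", perRoi = perRoi, centers = centers,
    totalCount = as.integer(sum(perRoi$count)), processedImages = imgs,
    paramsUsed = params, layout = layout)
}

# text anchor: centroid pixel of the ROI mask
.roiAnchor <- function(roi) {
  w <- which(roi@mask, arr.ind = TRUE)
  if (!nrow(w)) return(c(1L, 1L))
  c(as.integer(round(mean(w[, 1]))), as.integer(round(mean(w[, 2]))))
}

#' @describeIn enumeratePlate total CFU count accessor
#' @param result a `CountResult`
#' @export
totalCount <- function(result) result@totalCount

#' @describeIn enumeratePlate per-ROI summary table accessor
#' @export
perRoiCounts <- function(result) result@perRoi

#' @describeIn enumeratePlate detected center coordinates (list per ROI)
#' @export
centers <- function(result) result@centers

setMethod("show", "CountResult", function(object) {
  cat(sprintf("CountResult: %d CFU in %d ROI(s)\n", object@totalCount,
              nrow(object@perRoi)))
  for (i in seq_len(nrow(object@perRoi)))
    cat(sprintf("  %-12s %5d  (full-plate equivalent %d)\n",
      object@perRoi$label[i], object@perRoi$count[i],
      object@perRoi$fullPlateEquivalent[i]))
})

# 5x7 bitmap glyphs for digits, for font-free reproducible annotation
.digitGlyphs <- local({
  rows <- c(
    "0" = "01110 10001 10011 10101 11001 10001 01110",
    "1" = "00100 01100 00100 00100 00100 00100 01110",
    "2" = "01110 10001 00001 00010 00100 01000 11111",
    "3" = "11111 00010 00100 00010 00001 10001 01110",
    "4" = "00010 00110 01010 10010 11111 00010 00010",
    "5" = "11111 10000 11110 00001 00001 10001 01110",
    "6" = "00110 01000 10000 11110 10001 10001 01110",
    "7" = "11111 00001 00010 00100 01000 01000 01000",
    "8" = "01110 10001 10001 01110 10001 10001 01110",
    "9" = "01110 10001 10001 01111 00001 00010 01100")
  lapply(rows, function(s) {
    m <- do.call(rbind, lapply(strsplit(s, " ")[[1]], function(r)
      as.integer(strsplit(r, "")[[1]]) == 1L))
    m
  })
})

# stamp text (digits only) into a pixel matrix at (row, col), top-left
.stampText <- function(px, text, row, col, scale = 4L, value = 0L) {
  chars <- strsplit(text, "")[[1]]
  x <- col
  for (ch in chars) {
    g <- .digitGlyphs[[ch]]
    if (is.null(g)) { x <- x + 4L * scale; next }
    gm <- g[rep(seq_len(nrow(g)), each = scale),
            rep(seq_len(ncol(g)), each = scale)]
    ri <- row:(row + nrow(gm) - 1L)
    ci <- x:(x + ncol(gm) - 1L)
    ok <- ri >= 1L & ri <= nrow(px)
    okc <- ci >= 1L & ci <= ncol(px)
    sub <- px[ri[ok], ci[okc], drop = FALSE]
    sub[gm[ok, okc, drop = FALSE]] <- value
    px[ri[ok], ci[okc]] <- sub
    x <- x + 6L * scale
  }
  px
}

#' Annotate an original image with detection results
#'
#' Copies each detected center into the original image as a white spot
#' grown by `dilationSteps` rounds of 3x3 dilation (0 = single pixel,
#' 1 = 3x3, 2 = 5x5) and types each ROI's numeric count into the image
#' near the ROI, for the recommended final visual check of detection
#' performance on densely populated plates. Text uses a built-in 5x7
#' bitmap digit font so output is bit-reproducible without font
#' dependencies.
#'
#' @param original the unprocessed [GrayImage-class].
#' @param result a [CountResult-class] for that image.
#' @param dilationSteps 0, 1 or 2 (default 1).
#' @param drawCounts type the per-ROI counts into the image (default TRUE).
#' @param textScale integer magnification of the 5x7 digit font.
#' @return an annotated [GrayImage-class].
#' @export
annotateImage <- function(original, result, dilationSteps = 1,
                          drawCounts = TRUE, textScale = 4) {
  stopifnot(is(original, "GrayImage"), is(result, "CountResult"))
  if (!dilationSteps %in% 0:2)
    stop("'dilationSteps' must be 0, 1 or 2")
  px <- original@pixels
  k <- as.integer(dilationSteps)
  n <- nrow(px); m <- ncol(px)
  for (ctr in result@centers) {
    for (i in seq_len(nrow(ctr))) {
      ri <- max(1L, ctr$row[i] - k):min(n, ctr$row[i] + k)
      ci <- max(1L, ctr$col[i] - k):min(m, ctr$col[i] + k)
      px[ri, ci] <- 255L
    }
  }
  if (drawCounts) {
    for (i in seq_len(nrow(result@perRoi)))
      px <- .stampText(px, as.character(result@perRoi$count[i]),
        result@perRoi$anchorRow[i], result@perRoi$anchorCol[i],
        scale = as.integer(textScale))
  }
  initialize(original, pixels = px)
}

#' Write enumeration results as CSV
#'
#' One row per (image, ROI): `image`, `roi_label`, `count`,
#' `full_plate_equivalent`, `params` (a compact parameter signature so a
#' result row is traceable to its configuration).
#'
#' @param results named list of [CountResult-class] (names = image ids).
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeCountsCsv <- function(results, path) {
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(image = nm, roi_label = r@perRoi$label,
      count = r@perRoi$count,
      full_plate_equivalent = r@perRoi$fullPlateEquivalent,
      params = paramsSignature(r@paramsUsed), stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# compact, deterministic parameter signature for CSV traceability
paramsSignature <- function(p) {
  sprintf("ball%d-med%d-lift%d-prom%d-sat%.4g-%s", p@rollingBallRadiusPx,
    p@medianRadiusPx, p@brightnessLift, p@minProminence,
    p@contrastSaturationFraction,
    if (p@lightBackground) "light" else "dark")
}
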