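#' Describe the geometry of a plate image
#'
#' A plate is counted either as one full disc or as six wedge segments
#' (two replicate segments for each of three dilution levels). The
#' countable region always stops `rimInsetMm` short of the dish rim, where
#' colony clusters and the thicker broth layer would disturb both counting
#' and background brightness. Dish position is assumed fixed (jig +
#' predefined regions); the package does not detect the dish in the image.
#'
#' @param centerRow,centerCol dish center, 1-based pixel coordinates.
#' @param dishRadiusPx dish radius in pixels.
#' @param imageNrow,imageNcol image dimensions the layout applies to;
#'   default a square image just containing the dish.
#' @param nSegments 1 or 6.
#' @param rimInsetMm radial inset of the countable area, default 3 mm.
#' @param segmentGapDeg angular gap between wedges, default 4 degrees.
#' @param rotationDeg orientation of the first segment boundary
#'   (counter-clockwise, 0 = along +x).
#' @param pixelPitchUm micrometers per pixel, default 40.
#' @return a [PlateLayout-class].
#' @examples
#' lay <- plateLayout(650, 650, dishRadiusPx = 600, imageNrow = 1300,
#'                    imageNcol = 1300, nSegments = 6)
#' @export
plateLayout <- function(centerRow, centerCol, dishRadiusPx,
                        imageNrow = NULL, imageNcol = NULL, nSegments = 1,
                        rimInsetMm = 3, segmentGapDeg = 4, rotationDeg = 0,
                        pixelPitchUm = 40) {
  if (is.null(imageNrow)) imageNrow <- ceiling(centerRow + dishRadiusPx)
  if (is.null(imageNcol)) imageNcol <- ceiling(centerCol + dishRadiusPx)
  new("PlateLayout", centerRow = as.numeric(centerRow),
    centerCol = as.numeric(centerCol), dishRadiusPx = as.numeric(dishRadiusPx),
    nSegments = as.integer(nSegments), rimInsetMm = as.numeric(rimInsetMm),
    segmentGapDeg = as.numeric(segmentGapDeg),
    rotationDeg = as.numeric(rotationDeg),
    pixelPitchUm = as.numeric(pixelPitchUm),
    imageNrow = as.integer(imageNrow), imageNcol = as.integer(imageNcol))
}

#' Effective radius of the countable area
#'
#' Dish radius minus the rim inset converted to pixels.
#'
#' @param layout a [PlateLayout-class].
#' @return radius in pixels.
#' @export
effectiveRoiRadius <- function(layout) {
  layout@dishRadiusPx - layout@rimInsetMm * 1000 / layout@pixelPitchUm
}

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf(paste0(
    "PlateLayout: dish r=%.0f px at (%.0f, %.0f), %d segment(s),\n",
    "  rim inset %.1f mm -> countable r=%.0f px, image %d x %d px\n"),
    object@dishRadiusPx, object@centerRow, object@centerCol,
    object@nSegments, object@rimInsetMm, effectiveRoiRadius(object),
    object@imageNrow, object@imageNcol))
})

# polar coordinates of every pixel center relative to the dish center;
# angles counter-clockwise in degrees in [0, 360) with +x at 0 (row axis
# points down, so the sign of the row offset is flipped)
.polarGrid <- function(layout) {
  rows <- seq_len(layout@imageNrow) - layout@centerRow
  cols <- seq_len(layout@imageNcol) - layout@centerCol
  dr <- matrix(rows, layout@imageNrow, layout@imageNcol)
  dc <- matrix(cols, layout@imageNrow, layout@imageNcol, byrow = TRUE)
  list(rad = sqrt(dr^2 + dc^2),
       ang = (atan2(-dr, dc) * 180 / pi) %% 360)
}

#' Full-plate region of interest
#'
#' The disc of radius `dishRadiusPx - rimInsetMm` (in pixels) around the
#' dish center; `nSegments` of the layout is ignored.
#'
#' @param layout a [PlateLayout-class].
#' @return an [Roi-class] labelled `"full_plate"`.
#' @export
makeFullPlateRoi <- function(layout) {
  stopifnot(is(layout, "PlateLayout"))
  reff <- effectiveRoiRadius(layout)
  if (reff <= 0)
    stop("rim inset (", layout@rimInsetMm, " mm) leaves no countable area")
  g <- .polarGrid(layout)
  new("Roi", mask = g$rad <= reff, label = "full_plate")
}

#' Six-segment regions of interest
#'
#' Six disjoint wedges of equal angular extent (60 degrees minus the gap),
#' all inside the inset disc, labelled `segment_1 ... segment_6`
#' counter-clockwise from `rotationDeg`. The gap models the colony-free
#' border strips drawn on the dish bottom, which keep a colony from being
#' counted in two segments.
#'
#' @param layout a [PlateLayout-class] with `nSegments = 6`.
#' @return list of six [Roi-class] objects.
#' @export
makeSegmentRois <- function(layout) {
  stopifnot(is(layout, "PlateLayout"))
  if (layout@nSegments != 6L)
    stop("segment ROIs require a six-segment layout")
  if (layout@segmentGapDeg >= 60)
    stop("segment gap (", layout@segmentGapDeg, " deg) must be below 60 deg")
  reff <- effectiveRoiRadius(layout)
  if (reff <= 0)
    stop("rim inset (", layout@rimInsetMm, " mm) leaves no countable area")
  g <- .polarGrid(layout)
  inside <- g$rad <= reff & g$rad > 0  # exact center belongs to no wedge
  rel <- (g$ang - layout@rotationDeg) %% 360
  half <- layout@segmentGapDeg / 2
  lapply(seq_len(6L), function(k) {
    lo <- (k - 1) * 60 + half
    hi <- k * 60 - half
    # half-open angular interval: keeps wedges disjoint even at zero gap
    new("Roi", mask = inside & rel >= lo & rel < hi,
        label = sprintf("segment_%d", k))
  })
}

#' Scale a segment count to a full-plate equivalent
#'
#' Counts from a one-sixth segment are multiplied by 6 so they compare
#' directly with whole-plate enumerations.
#'
#' @param count non-negative integer CFU count.
#' @param nSegments 1 or 6 (segments per plate of the layout counted on).
#' @return `count * nSegments` as integer.
#' @examples
#' scaleSegmentCount(50, 6)  # 300
#' @export
scaleSegmentCount <- function(count, nSegments) {
  if (any(count < 0)) stop("counts must be >= 0")
  if (!all(nSegments %in% c(1, 6))) stop("nSegments must be 1 or 6")
  as.integer(count * nSegments)
}

#' Read a plate layout from a YAML or JSON config file
#'
#' Keys mirror the [plateLayout()] arguments (`center_row`, `center_col`,
#' `dish_radius_px`, `image_nrow`, `image_ncol`, `n_segments`,
#' `rim_inset_mm`, `segment_gap_deg`, `rotation_deg`, `pixel_pitch_um`).
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`; JSON is a YAML subset).
#' @return a [PlateLayout-class].
#' @export
readPlateLayout <- function(path) {
  if (!file.exists(path)) stop("layout config not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("center_row", "center_col", "dish_radius_px", "image_nrow",
             "image_ncol", "n_segments", "rim_inset_mm", "segment_gap_deg",
             "rotation_deg", "pixel_pitch_um")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown layout key(s): ", paste(bad, collapse = ", "))
  need <- c("center_row", "center_col", "dish_radius_px")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("layout config must define: ", paste(miss, collapse = ", "))
  get <- function(k, d) if (!is.null(cfg[[k]])) cfg[[k]] else d
  plateLayout(cfg$center_row, cfg$center_col, cfg$dish_radius_px,
    imageNrow = get("image_nrow", NULL), imageNcol = get("image_ncol", NULL),
    nSegments = get("n_segments", 1), rimInsetMm = get("rim_inset_mm", 3),
    segmentGapDeg = get("segment_gap_deg", 4),
    rotationDeg = get("rotation_deg", 0),
    pixelPitchUm = get("pixel_pitch_um", 40))
}
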