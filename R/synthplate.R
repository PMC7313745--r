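#' Specify a synthetic plate image
#'
#' Bundles the study conditions of a simulated plate: colony sizes and
#' contrasts, background level and smooth brightness gradient (variable
#' broth-layer thickness), sensor noise, and center-separation constraints.
#' Defaults emulate 24-h colonies on a backlit dish imaged at 40 um/px:
#' 0.5-2 mm near-opaque colonies (center darkness 130-200 gray levels below
#' a ~230 background), a +-15 gray-level polynomial background field, and
#' sigma = 3 sensor noise. The default minimum separation of twice the
#' largest diameter produces well-separated plates; reduce it to create
#' confluence.
#'
#' @param layout a [PlateLayout-class]; colonies are placed fully inside
#'   the ROI(s), emulating inoculation inside the drawn border lines.
#' @param nColonies total colony count, or one count per segment.
#' @param diameterRangeMm,darknessRange,backgroundLevel,gradientAmplitude,noiseSigma,minSeparationMm,profileExponent
#'   see [SyntheticPlateSpec-class].
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return a [SyntheticPlateSpec-class].
#' @export
syntheticPlateSpec <- function(layout, nColonies,
                               diameterRangeMm = c(0.5, 2),
                               darknessRange = c(130, 200),
                               backgroundLevel = 230,
                               gradientAmplitude = 15,
                               noiseSigma = 3,
                               minSeparationMm = 2 * max(diameterRangeMm),
                               profileExponent = 6,
                               seed = 1) {
  new("SyntheticPlateSpec", layout = layout,
    nColonies = as.integer(nColonies),
    diameterRangeMm = as.numeric(diameterRangeMm),
    darknessRange = as.numeric(darknessRange),
    backgroundLevel = as.numeric(backgroundLevel),
    gradientAmplitude = as.numeric(gradientAmplitude),
    noiseSigma = as.numeric(noiseSigma),
    minSeparationMm = as.numeric(minSeparationMm),
    profileExponent = as.numeric(profileExponent),
    seed = as.integer(seed))
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# analytic placement regions: a colony of radius rc (px) fits a region if
# its full disc lies inside the wedge/disc (keeps colonies out of the rim
# area and the border strips between segments, like the inoculation jig)
.placementTest <- function(layout, reff) {
  if (layout@nSegments == 1L) {
    list(full_plate = function(rad, relAng, rc) rad <= reff - rc)
  } else {
    half <- layout@segmentGapDeg / 2
    tests <- lapply(seq_len(6L), function(k) {
      lo <- (k - 1) * 60 + half
      hi <- k * 60 - half
      force(lo); force(hi)
      function(rad, relAng, rc) {
        a <- relAng - lo
        b <- hi - relAng
        a >= 0 & b >= 0 & rad <= reff - rc &
          rad * sin(pmin(a, 90) * pi / 180) >= rc &
          rad * sin(pmin(b, 90) * pi / 180) >= rc
      }
    })
    names(tests) <- sprintf("segment_%d", seq_len(6L))
    tests
  }
}

#' Generate a synthetic plate image with ground truth
#'
#' Renders `background + gradient - max(colony profiles) + noise`, rounded
#' and clamped to \[0, 255\]. Colony darkness profiles combine by per-pixel
#' maximum (colonies are opaque domes side by side, not stacked), so every
#' colony keeps exactly one darkest spot even under confluence. Placement
#' is uniform rejection sampling inside the ROI(s) honoring the
#' minimum-separation constraint; if a colony cannot be placed within
#' 10^4 attempts the packing is infeasible and an error is raised (never
#' silent truncation). Identical spec and seed give bit-identical output.
#'
#' @param spec a [SyntheticPlateSpec-class].
#' @return list with elements `image` ([GrayImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' lay <- plateLayout(150, 150, dishRadiusPx = 140, imageNrow = 300,
#'                    imageNcol = 300, rimInsetMm = 1)
#' p <- generatePlate(syntheticPlateSpec(lay, 5, seed = 7))
#' nrow(p$truth@centers)
#' @export
generatePlate <- function(spec) {
  stopifnot(is(spec, "SyntheticPlateSpec"))
  lay <- spec@layout
  reff <- effectiveRoiRadius(lay)
  tests <- .placementTest(lay, reff)
  nRoi <- length(tests)
  nPer <- if (length(spec@nColonies) == 1L && nRoi > 1L) {
    # one total over six segments: spread as evenly as possible
    base <- spec@nColonies %/% nRoi
    extra <- spec@nColonies %% nRoi
    as.integer(base + (seq_len(nRoi) <= extra))
  } else if (length(spec@nColonies) == 1L) {
    spec@nColonies
  } else {
    spec@nColonies
  }
  pitchMm <- lay@pixelPitchUm / 1000
  sepPx <- spec@minSeparationMm / pitchMm
  withSeed(spec@seed, {
    rows <- cols <- radii <- dark <- numeric(0)
    labs <- character(0)
    for (iRoi in seq_len(nRoi)) {
      for (j in seq_len(nPer[iRoi])) {
        dmm <- runif(1, spec@diameterRangeMm[1], spec@diameterRangeMm[2])
        rc <- dmm / 2 / pitchMm
        dk <- runif(1, spec@darknessRange[1], spec@darknessRange[2])
        placed <- FALSE
        for (att in seq_len(10000L)) {
          r0 <- round(runif(1, lay@centerRow - reff, lay@centerRow + reff))
          c0 <- round(runif(1, lay@centerCol - reff, lay@centerCol + reff))
          rad <- sqrt((r0 - lay@centerRow)^2 + (c0 - lay@centerCol)^2)
          ang <- (atan2(-(r0 - lay@centerRow), c0 - lay@centerCol) *
                    180 / pi - lay@rotationDeg) %% 360
          if (!tests[[iRoi]](rad, ang, rc)) next
          if (length(rows) &&
              min((rows - r0)^2 + (cols - c0)^2) < sepPx^2) next
          placed <- TRUE
          break
        }
        if (!placed)
          stop("packing infeasible: could not place colony ", j, " of ROI '",
               names(tests)[iRoi], "' after 10000 attempts ",
               "(too many colonies for the separation constraint)")
        rows <- c(rows, r0); cols <- c(cols, c0)
        radii <- c(radii, rc); dark <- c(dark, dk)
        labs <- c(labs, names(tests)[iRoi])
      }
    }
    img <- .renderPlate(lay, rows, cols, radii, dark, spec)
    truth <- new("GroundTruth",
      centers = data.frame(label = labs, row = as.integer(rows),
        col = as.integer(cols), radiusPx = radii, darkness = dark,
        stringsAsFactors = FALSE),
      nPerRoi = structure(as.integer(nPer), names = names(tests)))
    list(image = img, truth = truth)
  })
}

# render background field + colonies + noise into a GrayImage.
# consumes RNG draws: 5 gradient coefficients, 1 gradient scale, then the
# noise matrix (column-major)
.renderPlate <- function(lay, rows, cols, radii, dark, spec) {
  n <- lay@imageNrow; m <- lay@imageNcol
  u <- matrix((seq_len(m) - lay@centerCol) / lay@dishRadiusPx, n, m,
              byrow = TRUE)
  v <- matrix(-(seq_len(n) - lay@centerRow) / lay@dishRadiusPx, n, m)
  a <- runif(5, -1, 1)
  g <- a[1] * u + a[2] * v + a[3] * u * v + a[4] * u^2 + a[5] * v^2
  sc <- runif(1, 0.3, 1)
  if (max(abs(g)) > 0) g <- g / max(abs(g)) * spec@gradientAmplitude * sc
  field <- spec@backgroundLevel + g
  depth <- matrix(0, n, m)
  for (i in seq_along(rows)) {
    rc <- radii[i]
    ri <- max(1L, floor(rows[i] - rc)):min(n, ceiling(rows[i] + rc))
    ci <- max(1L, floor(cols[i] - rc)):min(m, ceiling(cols[i] + rc))
    rho <- sqrt(outer((ri - rows[i])^2, (ci - cols[i])^2, "+")) / rc
    prof <- dark[i] * (1 - rho^spec@profileExponent)
    prof[rho > 1 | prof < 0] <- 0
    depth[ri, ci] <- pmax(depth[ri, ci], prof)
  }
  px <- field - depth
  if (spec@noiseSigma > 0) px <- px + rnorm(n * m, 0, spec@noiseSigma)
  px <- roundHalfUp(px)
  px[px < 0] <- 0
  px[px > 255] <- 255
  grayImage(matrix(as.integer(px), n, m), pixelPitchUm = lay@pixelPitchUm)
}

#' Generate a pair of confluent colonies
#'
#' Renders exactly two colonies whose center distance is
#' `(1 - overlapFraction) * (r1 + r2)`, on a uniform background patch with
#' the spec's noise. Used to characterize how far two merging colonies can
#' still be resolved into two darkest cores (up to moderate overlap the
#' count stays 2; near-total overlap merges them into one dark region).
#'
#' @param spec a [SyntheticPlateSpec-class] (supplies diameters, darkness,
#'   background, noise and seed; its layout is not used).
#' @param overlapFraction in \[0, 1).
#' @return list with `image` ([GrayImage-class]) and `truth`
#'   ([GroundTruth-class]) holding the two centers.
#' @export
generateConfluentPair <- function(spec, overlapFraction) {
  stopifnot(is(spec, "SyntheticPlateSpec"))
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("overlapFraction must lie in [0, 1)")
  pitchMm <- spec@layout@pixelPitchUm / 1000
  withSeed(spec@seed, {
    # confluence is a grown-colony phenomenon between same-age neighbors:
    # render both colonies at the spec's largest diameter and mean darkness
    d <- rep(spec@diameterRangeMm[2], 2)
    dk <- rep(mean(spec@darknessRange), 2)
    rr <- d / 2 / pitchMm
    dist <- (1 - overlapFraction) * sum(rr)
    margin <- ceiling(max(rr)) + 12L
    m <- as.integer(2L * margin + ceiling(dist))
    n <- as.integer(2L * margin)
    mid <- n %/% 2L
    c1 <- margin
    c2 <- as.integer(margin + round(dist))
    depth <- matrix(0, n, m)
    for (i in 1:2) {
      cc <- if (i == 1) c1 else c2
      rho <- sqrt(outer((seq_len(n) - mid)^2, (seq_len(m) - cc)^2, "+")) /
        rr[i]
      prof <- dk[i] * (1 - rho^spec@profileExponent)
      prof[rho > 1 | prof < 0] <- 0
      depth <- pmax(depth, prof)
    }
    px <- spec@backgroundLevel - depth
    if (spec@noiseSigma > 0) px <- px + rnorm(n * m, 0, spec@noiseSigma)
    px <- roundHalfUp(px)
    px[px < 0] <- 0
    px[px > 255] <- 255
    img <- grayImage(matrix(as.integer(px), n, m),
                     pixelPitchUm = spec@layout@pixelPitchUm)
    truth <- new("GroundTruth",
      centers = data.frame(label = "pair", row = c(mid, mid),
        col = c(c1, c2), radiusPx = rr, darkness = dk,
        stringsAsFactors = FALSE),
      nPerRoi = c(pair = 2L))
    list(image = img, truth = truth)
  })
}

#' Write a ground-truth sidecar CSV
#'
#' Columns `roi_label`, `row_px`, `col_px` (1-based pixel coordinates).
#'
#' @param truth a [GroundTruth-class].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  df <- data.frame(roi_label = truth@centers$label,
                   row_px = truth@centers$row, col_px = truth@centers$col)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
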