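# End-to-end pipeline behavior on synthetic plates with known truth.

ctrLay <- function(n = 801, segments = 1)
  plateLayout((n + 1) / 2, (n + 1) / 2, dishRadiusPx = (n - 1) / 2 - 30,
              imageNrow = n, imageNcol = n, nSegments = segments)

test_that("a blank noisy plate yields zero centers", {
  lay <- ctrLay()
  p <- generatePlate(syntheticPlateSpec(lay, 0, seed = 6))
  res <- enumeratePlate(p$image, lay)
  expect_identical(totalCount(res), 0L)
})

test_that("well-separated colonies are recovered exactly, at their centers", {
  lay <- ctrLay()
  p <- generatePlate(syntheticPlateSpec(lay, 12, seed = 42))
  res <- enumeratePlate(p$image, lay)
  expect_identical(totalCount(res), 12L)
  got <- res@centers[["full_plate"]]
  truth <- p$truth@centers
  # every truth center has a detection within a few pixels (the detected
  # point is the centroid of a noise-perturbed quantization plateau)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((got$row - truth$row[i])^2 + (got$col - truth$col[i])^2)
    expect_lte(min(d), 6)
  }
})

test_that("two moderately confluent colonies still count as two", {
  spec <- syntheticPlateSpec(ctrLay(), 2, seed = 5)
  cp <- generateConfluentPair(spec, 0.3)
  res <- runPipeline(cp$image)
  expect_identical(nrow(res$centers), 2L)
})

test_that("segment plates report per-wedge counts and x6 equivalents", {
  lay6 <- ctrLay(1001, segments = 6)
  truthN <- c(3L, 4L, 5L, 3L, 4L, 5L)
  p <- generatePlate(syntheticPlateSpec(lay6, truthN, seed = 11,
                                        minSeparationMm = 2.5))
  res <- enumeratePlate(p$image, lay6)
  tab <- perRoiCounts(res)
  expect_identical(tab$count, truthN)
  expect_identical(tab$fullPlateEquivalent, truthN * 6L)
  expect_identical(totalCount(res), sum(truthN))
  # no center is attributed to two ROIs
  segs <- makeSegmentRois(lay6)
  for (k in seq_len(6)) {
    ck <- res@centers[[k]]
    expect_true(all(segs[[k]]@mask[cbind(ck$row, ck$col)]))
    others <- Reduce(`|`, lapply(segs[-k], slot, "mask"))
    expect_false(any(others[cbind(ck$row, ck$col)]))
  }
})

test_that("enumeration is bit-identical on repeated runs", {
  lay <- ctrLay()
  p <- generatePlate(syntheticPlateSpec(lay, 10, seed = 3))
  r1 <- enumeratePlate(p$image, lay)
  r2 <- enumeratePlate(p$image, lay)
  expect_identical(perRoiCounts(r1), perRoiCounts(r2))
  expect_identical(r1@centers, r2@centers)
  expect_identical(pixels(r1@processedImages[[1]]),
                   pixels(r2@processedImages[[1]]))
})

test_that("counts are invariant under a non-saturating brightness shift", {
  lay <- ctrLay()
  p <- generatePlate(syntheticPlateSpec(lay, 12, seed = 19,
    backgroundLevel = 210, gradientAmplitude = 8,
    darknessRange = c(120, 170)))
  base <- enumeratePlate(p$image, lay)
  for (shift in c(5L, 12L)) {
    px <- pixels(p$image) + shift
    expect_true(all(px >= shift & px <= 255L - shift))
    shifted <- enumeratePlate(grayImage(px), lay)
    expect_identical(totalCount(shifted), totalCount(base))
    expect_identical(perRoiCounts(shifted)$count, perRoiCounts(base)$count)
  }
})

test_that("full-plate counts are invariant under quarter-turn rotations", {
  lay <- ctrLay()  # square image, layout centered: rotations map ROI to itself
  p <- generatePlate(syntheticPlateSpec(lay, 9, seed = 23))
  n0 <- totalCount(enumeratePlate(p$image, lay))
  px <- pixels(p$image)
  for (k in 1:3) {
    px <- rot90(px)
    expect_identical(totalCount(enumeratePlate(grayImage(px), lay)), n0)
  }
})

test_that("image/layout mismatches are configuration errors", {
  lay <- ctrLay()
  img <- grayImage(matrix(230L, 100, 100))
  expect_error(enumeratePlate(img, lay), "do not match")
})

test_that("annotation marks centers as dilated white spots and types counts", {
  lay <- ctrLay()
  p <- generatePlate(syntheticPlateSpec(lay, 5, seed = 31))
  res <- enumeratePlate(p$image, lay)
  ctr <- res@centers[["full_plate"]]
  for (steps in 0:2) {
    ann <- annotateImage(p$image, res, dilationSteps = steps,
                         drawCounts = FALSE)
    px <- pixels(ann)
    for (i in seq_len(nrow(ctr))) {
      block <- px[(ctr$row[i] - steps):(ctr$row[i] + steps),
                  (ctr$col[i] - steps):(ctr$col[i] + steps)]
      expect_true(all(block == 255L))  # (2k+1)^2 white block per center
    }
    # outside spots and text the image is untouched
    changed <- which(px != pixels(p$image), arr.ind = TRUE)
    if (nrow(changed)) {
      dmin <- vapply(seq_len(nrow(changed)), function(j)
        min(pmax(abs(changed[j, 1] - ctr$row), abs(changed[j, 2] - ctr$col))),
        0)
      expect_true(all(dmin <= steps))
    }
  }
  expect_error(annotateImage(p$image, res, dilationSteps = 3), "0, 1 or 2")

  # zero centers: only the rendered "0" text differs from the original
  blank <- generatePlate(syntheticPlateSpec(lay, 0, seed = 2))
  res0 <- enumeratePlate(blank$image, lay)
  ann0 <- annotateImage(blank$image, res0, dilationSteps = 1)
  diffs <- sum(pixels(ann0) != pixels(blank$image))
  expect_gt(diffs, 0)          # the "0" glyph was stamped
  expect_lt(diffs, 5 * 7 * 16) # and nothing else
  expect_true(all(pixels(ann0)[pixels(ann0) != pixels(blank$image)] == 0L))
})

test_that("counts CSV has the documented schema", {
  lay <- ctrLay()
  p <- generatePlate(syntheticPlateSpec(lay, 6, seed = 37))
  res <- enumeratePlate(p$image, lay)
  f <- tempfile(fileext = ".csv")
  writeCountsCsv(list(plate_a = res), f)
  df <- read.csv(f, stringsAsFactors = FALSE)
  expect_identical(names(df), c("image", "roi_label", "count",
    "full_plate_equivalent", "params"))
  expect_identical(df$count, 6L)
  expect_identical(df$full_plate_equivalent, 6L)
  expect_match(df$params, "ball50-med6-lift135-prom10")
  unlink(f)
})
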