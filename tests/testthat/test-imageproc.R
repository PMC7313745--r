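# The five pixel operators, each against its exhaustive brute-force oracle
# plus the contracts that make the pipeline work.

test_that("background subtraction maps structureless surfaces to white", {
  for (v in c(0L, 77L, 255L)) {
    flat <- grayImage(matrix(v, 40, 40))
    expect_true(all(pixels(subtractBackground(flat, 15)) == 255L))
  }
})

test_that("background subtraction flattens a ramp but preserves small dark objects", {
  # linear ramp 80 -> 200 across columns with one 10-px dark disc
  ramp <- matrix(rep(as.integer(round(seq(80, 200, length.out = 64))),
                     each = 64), 64, 64)
  rr <- 32L; cc <- 20L
  inDisc <- (row(ramp) - rr)^2 + (col(ramp) - cc)^2 <= 25
  img <- ramp
  img[inDisc] <- img[inDisc] - 60L
  out <- pixels(subtractBackground(grayImage(img), 50))
  # oracle equality: exhaustive max/min over the ball footprint
  expect_identical(out, bruteSubtractBackground(img, 50))
  # ramp background flattened to white
  expect_true(all(out[!inDisc & (row(ramp) - rr)^2 +
                        (col(ramp) - cc)^2 > 64] == 255L))
  # disc survives at least 40 gray levels darker than its surround
  expect_gte(out[rr, cc + 10L] - out[rr, cc], 40L)
})

test_that("objects larger than the ball are treated as background", {
  sq <- matrix(200L, 200, 200)
  sq[26:175, 26:175] <- 60L   # 150-px square > 2 x radius 50
  out <- pixels(subtractBackground(grayImage(sq), 50))
  expect_identical(out, bruteSubtractBackground(sq, 50))
  expect_gte(out[100, 100], 200L)  # interior substantially lightened
})

test_that("background subtraction matches the brute-force oracle on random images", {
  set.seed(401)
  for (i in 1:4) {
    px <- pixels(randImage(24))
    expect_identical(pixels(subtractBackground(grayImage(px), 7)),
                     bruteSubtractBackground(px, 7))
    expect_identical(pixels(subtractBackground(grayImage(px), 7, FALSE)),
                     bruteSubtractBackground(px, 7, light = FALSE))
  }
})

test_that("dark-background mode maps background to black, keeps bright objects", {
  flat <- grayImage(matrix(40L, 30, 30))
  expect_true(all(pixels(subtractBackground(flat, 10, FALSE)) == 0L))
  px <- matrix(40L, 64, 64)
  px[30:34, 30:34] <- 180L
  out <- pixels(subtractBackground(grayImage(px), 20, FALSE))
  expect_gte(out[32, 32], 120L)
  expect_true(all(out[1:5, 1:5] <= 5L))
})

test_that("background subtraction validates its radius", {
  img <- randImage(20, seed = 4)
  expect_error(subtractBackground(img, 0), "radius")
  expect_error(subtractBackground(img, -3), "radius")
  expect_error(subtractBackground(img, 21), "exceeds")
})

test_that("auto contrast stretches percentile bounds to the full range", {
  # min 100, max 200 -> direct linear map with round-half-up
  px <- matrix(c(100L, 150L, 200L, 120L), 2, 2)
  out <- pixels(autoContrast(grayImage(px), 0))
  expect_identical(out, matrix(as.integer(floor((px - 100) * 255 / 100 + 0.5)),
                               2, 2))
  expect_identical(out[1, 1], 0L)
  expect_identical(out[1, 2], 255L)
  expect_identical(out[2, 1], 128L)  # 150 -> 127.5, rounded half-up
})

test_that("auto contrast is the identity on already-full or degenerate ranges", {
  px <- matrix(as.integer(c(0, 255, sample(0:255, 98, TRUE))), 10, 10)
  expect_identical(pixels(autoContrast(grayImage(px), 0)), px)
  const <- matrix(77L, 8, 8)
  expect_identical(pixels(autoContrast(grayImage(const), 0.003)), const)
  # a range within the noise floor is left alone rather than amplified
  narrow <- matrix(as.integer(240 + sample(0:10, 64, TRUE)), 8, 8)
  expect_identical(pixels(autoContrast(grayImage(narrow), 0)), narrow)
  expect_error(autoContrast(randImage(5, seed = 1), 0.5), "0, 0.5")
})

test_that("auto contrast depends only on the histogram (shift invariance)", {
  set.seed(42)
  px <- matrix(as.integer(sample(60:180, 400, TRUE)), 20, 20)
  out1 <- pixels(autoContrast(grayImage(px), 0.01))
  out2 <- pixels(autoContrast(grayImage(px + 30L), 0.01))
  expect_identical(out1, out2)
})

test_that("ROI-restricted contrast statistics ignore pixels outside the ROI", {
  px <- matrix(220L, 40, 40)
  px[15:25, 15:25] <- 100L
  px[1, 1] <- 0L  # an ink mark outside the ROI
  roi <- new("Roi", mask = (row(px) - 20)^2 + (col(px) - 20)^2 <= 15^2,
             label = "disc")
  out <- pixels(autoContrast(grayImage(px), 0, roi = roi))
  expect_identical(out[20, 20], 0L)   # ROI minimum maps to 0
  expect_identical(out[5, 20], 255L)  # ROI background maps to 255
})

test_that("median filter removes outliers and matches its exhaustive oracle", {
  const <- matrix(200L, 20, 20)
  expect_identical(pixels(medianFilter(grayImage(const), 6)), const)
  spike <- const; spike[10, 10] <- 0L
  expect_identical(pixels(medianFilter(grayImage(spike), 6)), const)
  set.seed(77)
  for (i in 1:3) {
    px <- pixels(randImage(32))
    expect_identical(pixels(medianFilter(grayImage(px), 6)),
                     bruteMedianDisc(px, 6))
  }
  px <- pixels(randImage(16, seed = 9))
  expect_identical(pixels(medianFilter(grayImage(px), 2)),
                   bruteMedianDisc(px, 2))
  expect_error(medianFilter(grayImage(px), 0), "radius")
})

test_that("brightness lift is saturating addition", {
  px <- matrix(c(50L, 120L, 255L, 0L), 2, 2)
  out <- pixels(liftBrightness(grayImage(px), 135))
  expect_identical(out, matrix(c(185L, 255L, 255L, 135L), 2, 2))
  expect_identical(pixels(liftBrightness(grayImage(px), 0)), px)
  img <- randImage(10, seed = 2)
  expect_true(all(pixels(liftBrightness(img, 255)) == 255L))
  expect_error(liftBrightness(img, -1), "delta")
  expect_error(liftBrightness(img, 300), "delta")
})

test_that("regional minima: flat fields and lifted background yield nothing", {
  expect_identical(nrow(findLocalMinima(grayImage(matrix(130L, 15, 15)), 1)),
                   0L)
  expect_identical(nrow(findLocalMinima(grayImage(matrix(255L, 15, 15)), 1)),
                   0L)
  # empty ROI
  img <- randImage(10, seed = 5)
  empty <- new("Roi", mask = matrix(FALSE, 10, 10), label = "empty")
  expect_identical(nrow(findLocalMinima(img, 1, roi = empty)), 0L)
})

test_that("one dark blob gives one center; two blobs give two", {
  px <- addBlob(matrix(255L, 21, 21), 11, 11, 8, 195)
  hits <- findLocalMinima(grayImage(px), 10)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$row, 11L)
  expect_identical(hits$col, 11L)
  expect_identical(as.numeric(hits),
                   as.numeric(bruteFindMinima(px, 10)[1, ]))

  px2 <- addBlob(matrix(255L, 21, 41), 11, 11, 8, 195)
  px2 <- addBlob(px2, 11, 31, 8, 175)   # saddle >= 95 between the blobs
  hits2 <- findLocalMinima(grayImage(px2), 10)
  expect_identical(nrow(hits2), 2L)
  expect_identical(hits2$col, c(11L, 31L))
  expect_equal(as.data.frame(lapply(hits2, as.numeric)),
               bruteFindMinima(px2, 10), ignore_attr = TRUE)
})

test_that("a flat plateau minimum yields exactly one centroid point", {
  px <- matrix(255L, 15, 15)
  px[6:9, 7:10] <- 80L   # 4x4 plateau
  hits <- findLocalMinima(grayImage(px), 10)
  expect_identical(nrow(hits), 1L)
  # centroid (7.5, 8.5): nearest plateau pixels tie, smallest row/col wins
  expect_identical(hits$row, 7L)
  expect_identical(hits$col, 8L)
})

test_that("minima detection matches the exhaustive prominence oracle", {
  skip_if_not_installed("igraph")
  set.seed(501)
  for (i in 1:8) {
    px <- pixels(randImage(32, levels = seq(0L, 255L, by = 17L)))
    got <- findLocalMinima(grayImage(px), 20)
    want <- bruteFindMinima(px, 20)
    expect_equal(as.data.frame(lapply(got, as.numeric)), want,
                 ignore_attr = TRUE)
  }
  # with a mask
  px <- pixels(randImage(24, levels = seq(0L, 250L, by = 25L)))
  mask <- (row(px) - 12)^2 + (col(px) - 12)^2 <= 100
  roi <- new("Roi", mask = mask, label = "disc")
  got <- findLocalMinima(grayImage(px), 15, roi = roi)
  want <- bruteFindMinima(px, 15, mask = mask)
  expect_equal(as.data.frame(lapply(got, as.numeric)), want,
               ignore_attr = TRUE)
})

test_that("the number of minima is non-increasing in the prominence threshold", {
  set.seed(33)
  for (i in 1:4) {
    img <- randImage(28, levels = seq(0L, 255L, by = 15L))
    counts <- vapply(c(1, 5, 10, 20, 40, 80, 160),
                     function(p) nrow(findLocalMinima(img, p)), 0L)
    expect_true(all(diff(counts) <= 0L))
  }
})

test_that("minima counts are invariant under rotations and flips", {
  set.seed(91)
  for (i in 1:3) {
    px <- pixels(randImage(26, levels = seq(0L, 255L, by = 17L)))
    n0 <- nrow(findLocalMinima(grayImage(px), 12))
    expect_identical(nrow(findLocalMinima(grayImage(rot90(px)), 12)), n0)
    expect_identical(nrow(findLocalMinima(grayImage(px[nrow(px):1, ]), 12)),
                     n0)
    expect_identical(nrow(findLocalMinima(grayImage(px[, ncol(px):1]), 12)),
                     n0)
  }
  # exact coordinate transform on a tie-free fixture
  px <- addBlob(matrix(255L, 20, 30), 6, 21, 5, 180)
  h0 <- findLocalMinima(grayImage(px), 10)
  h90 <- findLocalMinima(grayImage(rot90(px)), 10)
  expect_identical(nrow(h90), 1L)
  expect_identical(h90$row, ncol(px) + 1L - h0$col)
  expect_identical(h90$col, h0$row)
})

test_that("all operators preserve shape, range and are deterministic", {
  set.seed(71)
  img <- randImage(30, 22)
  ops <- list(
    function(x) subtractBackground(x, 9),
    function(x) autoContrast(x, 0.01),
    function(x) medianFilter(x, 3),
    function(x) liftBrightness(x, 135))
  for (op in ops) {
    out <- op(img)
    expect_identical(dim(out), dim(img))
    expect_true(all(pixels(out) >= 0L & pixels(out) <= 255L))
    expect_identical(pixels(op(img)), pixels(out))  # bit-identical rerun
  }
  h1 <- findLocalMinima(img, 10)
  expect_identical(findLocalMinima(img, 10), h1)
})
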