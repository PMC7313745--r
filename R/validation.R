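#' Load the packaged method-comparison enumeration table
#'
#' Twenty-five plate samples enumerated three times each by three methods:
#' the on-screen point-and-click reference ("gold standard"), manual pen
#' marking on the dish lid, and the automatic pipeline (deterministic, so
#' no repeats). Counts are full-plate equivalents (segment counts already
#' scaled by 6); rates are markings per second. The ratio columns are
#' recomputed from the count columns (rounded half-up to 2 decimals), so
#' they are reproducible from the data by construction.
#'
#' @param path CSV file; defaults to the packaged transcription.
#' @return data.frame with one row per sample and columns `sample_id`,
#'   `gold_rate_mean`, `gold_rate_sd`, `gold_count_mean`, `gold_count_sd`,
#'   `manual_rate_mean`, `manual_rate_sd`, `manual_count_mean`,
#'   `manual_count_sd`, `auto_count`, `ratio_auto`, `ratio_manual`,
#'   `segments_per_plate`.
#' @export
loadTable1 <- function(path = system.file("extdata",
                         "enumeration_comparison.csv",
                         package = "colonycount")) {
  if (!nzchar(path) || !file.exists(path))
    stop("enumeration table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gold_rate_mean", "gold_rate_sd", "gold_count_mean",
    "gold_count_sd", "manual_rate_mean", "manual_rate_sd",
    "manual_count_mean", "manual_count_sd", "auto_count", "ratio_auto",
    "ratio_manual", "segments_per_plate")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed enumeration table, missing column(s): ",
         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (any(is.na(unlist(r))))
      stop("malformed enumeration table: NA in row ", i)
    if (r$gold_count_mean < 0 || r$manual_count_mean < 0 || r$auto_count < 0 ||
        r$gold_count_sd < 0 || r$manual_count_sd < 0)
      stop("malformed enumeration table: negative count/SD in row ", i)
    if (!(r$segments_per_plate %in% c(1, 6)))
      stop("malformed enumeration table: segments_per_plate must be 1 or 6 ",
           "in row ", i)
  }
  tab
}

#' Mean variation coefficient of repeated enumerations
#'
#' Average of `sd / mean` over samples, as a percentage: how repeatable a
#' counting method is across its three enumerations of the same plate.
#'
#' @param means,sds numeric vectors of per-sample means and SDs.
#' @return mean variation coefficient in percent (unrounded).
#' @examples
#' meanVariationCoefficient(c(100, 200), c(1, 4))  # 1.5
#' @export
meanVariationCoefficient <- function(means, sds) {
  if (length(means) != length(sds)) stop("means and sds must match in length")
  if (!length(means)) stop("empty input")
  if (any(means <= 0)) stop("variation coefficient needs positive means")
  if (any(sds < 0)) stop("SDs must be >= 0")
  mean(sds / means) * 100
}

#' Mean counting rate
#'
#' Arithmetic mean of per-sample mean counting rates (markings per second).
#'
#' @param rates numeric vector of per-sample mean rates.
#' @return mean rate in counts/s (unrounded; report to 1 decimal).
#' @export
meanRate <- function(rates) {
  if (!length(rates)) stop("empty input")
  mean(rates)
}

# effective-variance chi-square of the origin-constrained line y = b x:
# each residual is normalized by the x-error projected through the line
# plus the y-error, with relative errors cvX and cvY
.evChisq <- function(b, x, y, cvX, cvY) {
  sum((y - b * x)^2 / ((b * cvX * x)^2 + (cvY * y)^2))
}

#' Error-weighted regression through the origin
#'
#' Fits `y = b * x` by minimizing the effective-variance chi-square
#' `sum((y - b x)^2 / ((b cvX x)^2 + (cvY y)^2))` over `b > 0`: an
#' errors-in-variables fit in which each point carries an assigned
#' *relative* error on x and on y (average variation coefficients are used
#' because individual repeat SDs can be zero, which would give infinite
#' weight). The line is forced through the origin because two counting
#' methods must agree at zero colonies. The minimum is located by Brent
#' search (a single parameter survives the origin constraint) to a
#' tolerance of 1e-10 on `b`; the 95% CI comes from the curvature of the
#' chi-square at its minimum (slope +- 1.96 standard errors).
#'
#' @param x reference counts (all > 0).
#' @param y comparison counts.
#' @param cvX,cvY assigned relative errors (e.g. 0.01 for 1%).
#' @return a [RegressionResult-class].
#' @examples
#' r <- originRegression(c(100, 200, 400), c(205, 401, 797), 0.01, 0.05)
#' slope(r)
#' @export
originRegression <- function(x, y, cvX, cvY) {
  if (length(x) != length(y)) stop("x and y must match in length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (any(x <= 0)) stop("reference counts must be positive")
  if (any(y < 0)) stop("counts must be >= 0")
  if (cvX <= 0 || cvY <= 0) stop("relative errors must be positive")
  hi <- 4 * max(y / x) + 1
  opt <- optimize(.evChisq, c(1e-8, hi), x = x, y = y, cvX = cvX, cvY = cvY,
                  tol = 1e-10)
  b <- opt$minimum
  if (hi - b < 1e-6)
    stop("origin regression did not converge inside the search bracket")
  h <- max(1e-6 * b, 1e-9)
  d2 <- (.evChisq(b + h, x, y, cvX, cvY) - 2 * opt$objective +
         .evChisq(b - h, x, y, cvX, cvY)) / h^2
  se <- if (d2 > 0) sqrt(2 / d2) else NA_real_
  new("RegressionResult", slope = b, se = se,
    ci95Low = b - 1.96 * se, ci95High = b + 1.96 * se,
    cvX = cvX, cvY = cvY, nPoints = length(x), chisqMin = opt$objective)
}

#' @describeIn originRegression fitted slope accessor
#' @param r a `RegressionResult`
#' @export
slope <- function(r) r@slope

#' @describeIn originRegression 95% confidence interval accessor
#' @export
ci95 <- function(r) c(r@ci95Low, r@ci95High)

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(paste0(
    "Origin-constrained effective-variance regression (n = %d)\n",
    "  slope %.3f, CI95 (%.3f, %.3f), assigned errors x %.1f%% / y %.1f%%\n"),
    object@nPoints, object@slope, object@ci95Low, object@ci95High,
    100 * object@cvX, 100 * object@cvY))
})

#' Correction factor to reach reference-equivalent counts
#'
#' The reciprocal of the fitted slope at its reported 3-decimal precision:
#' multiplying a method's counts by this factor makes them equivalent to
#' the reference on average.
#'
#' @param r a [RegressionResult-class] (or a bare slope).
#' @return `1 / round(slope, 3)`, rounded to 3 decimals.
#' @examples
#' correctionFactor(0.976)  # 1.025
#' @export
correctionFactor <- function(r) {
  b <- if (is(r, "RegressionResult")) r@slope else r
  if (!is.numeric(b) || b <= 0) stop("slope must be positive")
  round(1 / round(b, 3), 3)
}

#' Method-comparison report over the enumeration table
#'
#' Recomputes every summary statistic of the comparison study from the
#' table: the two origin-constrained regressions (automatic and manual
#' counts against the reference, with 1% reference error, 0.1% automatic
#' error and 5% manual error), their correction factors, mean variation
#' coefficients, and mean counting rates.
#'
#' @param tab enumeration table from [loadTable1()].
#' @return list with elements `auto` and `manual`
#'   ([RegressionResult-class]), `factorAuto`, `factorManual`,
#'   `cvGoldPct`, `cvManualPct`, `rateGold`, `rateManual`.
#' @export
validationReport <- function(tab = loadTable1()) {
  auto <- originRegression(tab$gold_count_mean, tab$auto_count,
                           cvX = 0.01, cvY = 0.001)
  man <- originRegression(tab$gold_count_mean, tab$manual_count_mean,
                          cvX = 0.01, cvY = 0.05)
  list(auto = auto, manual = man,
    factorAuto = correctionFactor(auto), factorManual = correctionFactor(man),
    cvGoldPct = meanVariationCoefficient(tab$gold_count_mean,
                                         tab$gold_count_sd),
    cvManualPct = meanVariationCoefficient(tab$manual_count_mean,
                                           tab$manual_count_sd),
    rateGold = meanRate(tab$gold_rate_mean),
    rateManual = meanRate(tab$manual_rate_mean))
}
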