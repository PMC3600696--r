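#' Lean-meat percentage from Fat-o-Meat'er probe measurements
#'
#' Predicts carcass lean-meat percentage from two backfat depths and one
#' muscle depth (all in mm):
#' `66.7393 - 0.2655 x1 - 0.5432 x2 + 0.0838 x3`.
#'
#' @param x1 Backfat depth at position 1 (third/fourth lumbar vertebra), mm.
#' @param x2 Backfat depth at position 2 (third/fourth last rib), mm.
#' @param x3 Muscle depth at position 2, mm.
#' @return Predicted meat percentage; vectorized elementwise.
#' @examples
#' meat_percentage(0, 0, 0) # the intercept, 66.7393
#' @export
meat_percentage <- function(x1, x2, x3) {
  for (v in list(x1, x2, x3)) {
    if (any(v < 0, na.rm = TRUE)) stop("probe measurements must be non-negative")
    if (any(!is.finite(v) & !is.na(v))) stop("probe measurements must be finite")
  }
  66.7393 - 0.2655 * x1 - 0.5432 * x2 + 0.0838 * x3
}

#' Mask probe measurements taken at high reflectance
#'
#' Optical fat/muscle probes misread very fat carcasses; measurements with
#' reflectance strictly above 65 are set to missing, all others pass through
#' unchanged.
#'
#' @param values Measurement vector.
#' @param reflectance Reflectance vector, same length.
#' @return `values` with entries at `reflectance > 65` replaced by `NA`.
#' @export
reflectance_filter <- function(values, reflectance) {
  if (length(values) != length(reflectance)) {
    stop("values and reflectance must have equal length")
  }
  values[!is.na(reflectance) & reflectance > 65] <- NA
  values
}

#' Body mass index
#'
#' `weight / length^2` with weight in kg and length in metres (the human
#' convention, which reproduces the magnitudes of the reference tables when
#' body length is measured rump to shoulder blade).
#'
#' @param weight Body weight, kg.
#' @param length Body length, metres; must be positive.
#' @return BMI, kg/m^2.
#' @export
bmi <- function(weight, length) {
  if (any(length <= 0, na.rm = TRUE)) stop("length must be positive")
  weight / length^2
}

#' Body adiposity index
#'
#' `abdominal_circumference / length^1.5`, both in cm.
#'
#' @param abdominal_circumference Abdominal circumference at the navel, cm.
#' @param length Body length, cm; must be positive.
#' @return BAI, cm/cm^1.5.
#' @export
bai <- function(abdominal_circumference, length) {
  if (any(length <= 0, na.rm = TRUE)) stop("length must be positive")
  abdominal_circumference / length^1.5
}

#' Daily gains over the growth period
#'
#' Computes average daily gain over the whole period (first to last record),
#' pre-weaning gain (first record to the recorded weight nearest the weaning
#' age) and post-weaning gain (that record to the last). Intervals that are
#' not covered by at least two distinct records give `NA` rather than an
#' error.
#'
#' @param ages Strictly increasing record ages, days.
#' @param weights Weights at those ages, kg.
#' @param weaning_age Nominal weaning age, days; the segment boundary is the
#'   recorded timepoint nearest to it (default 42 days, i.e. the five/six
#'   week record in the reference schedule).
#' @return A one-row tibble with `adg`, `dgi`, `dgii` (kg/day).
#' @examples
#' daily_gains(c(0, 36, 215), c(0.8, 16.64, 95.4)) # linear growth: all 0.44
#' @export
daily_gains <- function(ages, weights, weaning_age = 42) {
  keep <- !is.na(ages) & !is.na(weights)
  ages <- ages[keep]
  weights <- weights[keep]
  if (is.unsorted(ages, strictly = TRUE)) stop("ages must be strictly increasing")
  n <- length(ages)
  slope <- function(i, j) {
    if (is.na(i) || is.na(j) || j <= i) return(NA_real_)
    (weights[j] - weights[i]) / (ages[j] - ages[i])
  }
  if (n < 2) {
    return(tibble::tibble(adg = NA_real_, dgi = NA_real_, dgii = NA_real_))
  }
  b <- which.min(abs(ages - weaning_age))
  tibble::tibble(
    adg = slope(1L, n),
    dgi = slope(1L, b),
    dgii = slope(b, n)
  )
}

#' Transform trait values toward normality
#'
#' @param values Numeric vector; `NA` propagates.
#' @param kind `"log10"` (requires positive values) or `"sqrt"` (requires
#'   non-negative values).
#' @return Transformed vector.
#' @export
transform_values <- function(values, kind = c("log10", "sqrt", "none")) {
  kind <- match.arg(kind)
  ok <- !is.na(values)
  bad <- switch(kind,
    log10 = which(ok & values <= 0),
    sqrt = which(ok & values < 0),
    none = integer(0)
  )
  if (length(bad) > 0) {
    stop("values outside the ", kind, " domain at index(es): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  switch(kind,
    log10 = log10(values),
    sqrt = sqrt(values),
    none = values
  )
}

#' Back-transform values
#'
#' Inverse of [transform_values()]; round trips are exact to numerical
#' precision on valid domains.
#'
#' @inheritParams transform_values
#' @export
inverse_transform <- function(values, kind = c("log10", "sqrt", "none")) {
  kind <- match.arg(kind)
  switch(kind, log10 = 10^values, sqrt = values^2, none = values)
}

#' Descriptive statistics for one trait
#'
#' Mean, sample SD (n-1 denominator), range and coefficient of variation
#' (`100 sd/mean`), over non-missing values.
#'
#' @param values Numeric vector with at least two non-missing values.
#' @return A one-row tibble: `n`, `mean`, `sd`, `min`, `max`, `cv_percent`.
#' @export
descriptive_stats <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least two non-missing values")
  m <- mean(v)
  s <- stats::sd(v)
  tibble::tibble(
    n = length(v), mean = m, sd = s, min = min(v), max = max(v),
    cv_percent = 100 * s / m
  )
}

#' Descriptive table across traits
#'
#' One row per trait, in the shape of a summary table (N, mean, SD, min,
#' max, CV%).
#'
#' @param data A data frame of phenotypes.
#' @param traits Character vector of trait column names.
#' @return A tibble with one row per trait.
#' @export
describe_traits <- function(data, traits) {
  purrr::map_dfr(traits, function(tr) {
    dplyr::bind_cols(tibble::tibble(trait = tr), descriptive_stats(data[[tr]]))
  })
}

#' Flag extreme values for manual review
#'
#' Data-exploration aid: flags values more than `k` sample SDs from the
#' mean. No automatic exclusion is applied.
#'
#' @param values Numeric vector.
#' @param k SD multiple (default 4).
#' @return Integer indices of flagged values.
#' @export
flag_outliers <- function(values, k = 4) {
  v <- values
  m <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  which(!is.na(v) & abs(v - m) > k * s)
}
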