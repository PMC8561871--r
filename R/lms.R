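# Growth-reference engine: LMS tables, z-scores/percentiles, age interpolation,
# and the percent-of-adult-height reference curve.

.LMS_L_TOL <- 1e-7  # |L| below this uses the log (L -> 0) limit of the transform

#' Construct an LMS growth-reference table
#'
#' An LMS reference summarises the distribution of a measurement (height or
#' BMI) at each age by a Box-Cox power `L`, median `M` and coefficient of
#' variation `S`. Ages are decimal years and must be strictly increasing;
#' queries between grid ages are linearly interpolated, queries outside the
#' span fail rather than extrapolate.
#'
#' @param age Numeric vector of ages (decimal years), strictly increasing.
#' @param L,M,S Numeric vectors of the same length as `age`; `M` and `S`
#'   must be positive.
#' @param sex `"male"` or `"female"`.
#' @param measurement `"height"` (cm) or `"bmi"` (kg/m^2).
#' @return A data frame of class `"lms_table"` with columns `age`, `L`, `M`,
#'   `S` and attributes `sex` and `measurement`.
#' @seealso [lms_lookup()], [lms_zscore()], [read_lms_reference()]
#' @export
lms_table <- function(age, L, M, S, sex = c("male", "female"),
                      measurement = c("height", "bmi")) {
  sex <- match.arg(sex)
  measurement <- match.arg(measurement)
  n <- length(age)
  if (n < 2L) stop("an LMS reference needs at least two age rows")
  if (length(L) != n || length(M) != n || length(S) != n)
    stop("age, L, M and S must have equal length")
  if (anyNA(c(age, L, M, S))) stop("LMS reference values must be non-missing")
  if (any(diff(age) <= 0)) stop("reference ages must be strictly increasing")
  if (any(M <= 0)) stop("reference M values must be positive")
  if (any(S <= 0)) stop("reference S values must be positive")
  structure(data.frame(age = age, L = L, M = M, S = S),
            sex = sex, measurement = measurement,
            class = c("lms_table", "data.frame"))
}

#' @export
print.lms_table <- function(x, ...) {
  cat(sprintf("LMS reference: %s, %s; %d rows spanning ages %.2f-%.2f y\n",
              attr(x, "measurement"), attr(x, "sex"), nrow(x),
              min(x$age), max(x$age)))
  invisible(x)
}

#' LMS z-score of a measurement
#'
#' Standardises a measurement against reference parameters:
#' `z = ((value/M)^L - 1) / (L * S)` for `|L|` away from zero, and the limit
#' `log(value/M) / S` when `L` is (numerically) zero.
#'
#' @param value Positive measurement value(s).
#' @param L,M,S Reference parameters (recycled against `value`); `M`, `S` > 0.
#' @return z-score(s), unitless.
#' @examples
#' lms_zscore(22, L = 1, M = 20, S = 0.1)  # 1
#' @export
lms_zscore <- function(value, L, M, S) {
  if (anyNA(value) || any(value <= 0)) stop("measurement values must be positive")
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  n <- max(length(value), length(L), length(M), length(S))
  value <- rep_len(value, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) > .LMS_L_TOL,
         ((value / M)^L - 1) / (L * S),
         log(value / M) / S)
}

#' Invert an LMS z-score back to the measurement scale
#'
#' @param z z-score(s).
#' @param L,M,S Reference parameters; `M`, `S` > 0.
#' @return Measurement value(s) such that [lms_zscore()] recovers `z`.
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  base <- 1 + L * S * z
  bad <- abs(L) > .LMS_L_TOL & base <= 0
  if (any(bad))
    stop("z-score outside the support of the Box-Cox reference distribution")
  ifelse(abs(L) > .LMS_L_TOL, M * base^(1 / L), M * exp(S * z))
}

#' Convert between z-scores and percentiles
#'
#' `zscore_to_percentile()` is `100 * pnorm(z)`; `percentile_to_zscore()` is
#' its inverse. Percentiles are on (0, 100).
#'
#' @param z Finite z-score(s).
#' @param percentile Percentile(s) in (0, 100).
#' @return Percentile(s), or z-score(s).
#' @export
zscore_to_percentile <- function(z) {
  if (anyNA(z) || any(!is.finite(z))) stop("z must be finite")
  100 * stats::pnorm(z)
}

#' @rdname zscore_to_percentile
#' @export
percentile_to_zscore <- function(percentile) {
  if (anyNA(percentile) || any(percentile <= 0) || any(percentile >= 100))
    stop("percentiles must lie strictly between 0 and 100")
  stats::qnorm(percentile / 100)
}

#' Interpolate reference parameters at arbitrary ages
#'
#' `L`, `M` and `S` are each linearly interpolated between the bracketing grid
#' rows; a query at a grid age returns that row exactly. Queries outside the
#' table's age span raise an error (no extrapolation).
#'
#' @param table An [lms_table()].
#' @param age Age(s) in decimal years, within the table span.
#' @return A list with numeric components `L`, `M`, `S` matching `age`.
#' @export
lms_lookup <- function(table, age) {
  stopifnot(inherits(table, "lms_table"))
  if (anyNA(age)) stop("age must be non-missing")
  rng <- range(table$age)
  if (any(age < rng[1] | age > rng[2]))
    stop(sprintf("age outside the reference span [%.2f, %.2f] years",
                 rng[1], rng[2]))
  list(L = stats::approx(table$age, table$L, xout = age)$y,
       M = stats::approx(table$age, table$M, xout = age)$y,
       S = stats::approx(table$age, table$S, xout = age)$y)
}

#' Measurement value at a given z-score and age
#'
#' Convenience inverse lookup: interpolates the reference at `age` and maps a
#' z-score to the measurement scale.
#'
#' @inheritParams lms_lookup
#' @param z z-score(s), recycled against `age`.
#' @return Measurement value(s).
#' @export
lms_value <- function(table, age, z) {
  p <- lms_lookup(table, age)
  lms_inverse(z, p$L, p$M, p$S)
}

#' Adult mean stature norms
#'
#' Mean stature attained at and above 18 years, used as the denominator of the
#' percent-of-adult-height reference. Defaults are 177.6 cm (males) and
#' 163.7 cm (females).
#'
#' @param male,female Mean adult stature in cm; must lie in (140, 220).
#' @return A named list of class `"adult_norms"`.
#' @export
adult_norms <- function(male = 177.6, female = 163.7) {
  for (v in c(male, female))
    if (!is.finite(v) || v <= 140 || v >= 220)
      stop("adult mean statures must lie in (140, 220) cm")
  structure(list(male = male, female = female), class = "adult_norms")
}

#' Build a percent-of-adult-height reference curve
#'
#' For each age on the height reference grid, the mean percent of adult height
#' attained is `100 * M(age) / mean adult stature` for that sex. The curve is
#' the substrate for biological-age inverse lookup: a child's attained percent
#' is located on it to read off the age at which the average child reaches the
#' same percent.
#'
#' @param height_table An [lms_table()] with `measurement = "height"`.
#' @param norms An [adult_norms()] object.
#' @return A data frame of class `"pah_reference"` with columns `age` and
#'   `percent`, and a `sex` attribute.
#' @export
build_pah_reference <- function(height_table, norms) {
  stopifnot(inherits(height_table, "lms_table"))
  if (attr(height_table, "measurement") != "height")
    stop("percent-adult-height reference requires a height table")
  if (!inherits(norms, "adult_norms")) stop("norms must be an adult_norms object")
  sex <- attr(height_table, "sex")
  pct <- 100 * height_table$M / norms[[sex]]
  if (any(diff(pct) < 0))
    stop("reference median height must be non-decreasing with age")
  if (max(pct) > 100 + 1e-9)
    stop("adult norm lies below the reference median at the oldest ages")
  structure(data.frame(age = height_table$age, percent = pmin(pct, 100)),
            sex = sex, class = c("pah_reference", "data.frame"))
}

#' @export
print.pah_reference <- function(x, ...) {
  cat(sprintf(
    "Percent-adult-height reference (%s): ages %.2f-%.2f y, %.1f%%-%.1f%%\n",
    attr(x, "sex"), min(x$age), max(x$age), min(x$percent), max(x$percent)))
  invisible(x)
}

#' Mean percent of adult height at given ages
#'
#' @param reference A [build_pah_reference()] result.
#' @param age Age(s) within the reference span.
#' @return Percent(s) of adult height.
#' @export
pah_at_age <- function(reference, age) {
  stopifnot(inherits(reference, "pah_reference"))
  rng <- range(reference$age)
  if (any(age < rng[1] | age > rng[2]))
    stop(sprintf("age outside the reference span [%.2f, %.2f] years",
                 rng[1], rng[2]))
  stats::approx(reference$age, reference$percent, xout = age)$y
}

#' Read / write LMS reference files
#'
#' Delimited text with header `measurement,sex,age_years,L,M,S`. A file may
#' hold several (measurement, sex) blocks; `read_lms_reference()` returns a
#' nested list `tables[[measurement]][[sex]]` of [lms_table()] objects.
#'
#' @param path File path.
#' @param tables For writing: a nested list as returned by reading.
#' @param sep Field separator (default comma).
#' @return For reading, a nested list of `lms_table`s; for writing, `path`
#'   invisibly.
#' @export
read_lms_reference <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("measurement", "sex", "age_years", "L", "M", "S")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("reference file is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (m in unique(d$measurement)) {
    for (s in unique(d$sex[d$measurement == m])) {
      b <- d[d$measurement == m & d$sex == s, ]
      b <- b[order(b$age_years), ]
      out[[m]][[s]] <- lms_table(b$age_years, b$L, b$M, b$S,
                                 sex = s, measurement = m)
    }
  }
  out
}

#' Read / write percent-adult-height reference files
#'
#' Delimited text with header `sex,age_years,percent`; one curve per sex.
#'
#' @param path File path.
#' @param curves For writing: a named list of [build_pah_reference()]-style
#'   curves.
#' @param sep Field separator.
#' @return For reading, a named list of `pah_reference` curves; for
#'   writing, `path` invisibly.
#' @export
read_pah_reference <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sex", "age_years", "percent")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("reference file is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(d$sex)) {
    b <- d[d$sex == s, ]
    b <- b[order(b$age_years), ]
    if (any(diff(b$percent) < 0))
      stop("percent must be non-decreasing with age")
    if (max(b$percent) > 100) stop("percent must not exceed 100")
    out[[s]] <- structure(data.frame(age = b$age_years, percent = b$percent),
                          sex = s, class = c("pah_reference", "data.frame"))
  }
  out
}

#' @rdname read_pah_reference
#' @export
write_pah_reference <- function(curves, path, sep = ",") {
  rows <- lapply(names(curves), function(s)
    data.frame(sex = s, age_years = curves[[s]]$age,
               percent = curves[[s]]$percent))
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_lms_reference
#' @export
write_lms_reference <- function(tables, path, sep = ",") {
  rows <- list()
  for (m in names(tables)) {
    for (s in names(tables[[m]])) {
      t <- tables[[m]][[s]]
      rows[[paste(m, s)]] <- data.frame(measurement = m, sex = s,
                                        age_years = t$age, L = t$L,
                                        M = t$M, S = t$S)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
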