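# Somatic maturity estimation: predicted adult height, percent attained,
# biological age by inverse reference lookup, maturity-timing class.

#' Construct a Khamis-Roche-style coefficient table
#'
#' Age- and sex-specific linear coefficients for predicting adult stature from
#' current stature, weight and mid-parent stature:
#' `predicted = intercept + b_stature * stature + b_weight * weight +
#' b_midparent * midparent`. Coefficients are linearly interpolated to the
#' query age; no extrapolation beyond the table span.
#'
#' @param age Ages (decimal years), strictly increasing, at least 2 rows.
#' @param intercept Intercepts (cm).
#' @param beta_stature Unitless stature coefficients.
#' @param beta_weight Weight coefficients (cm per kg).
#' @param beta_midparent Unitless mid-parent stature coefficients.
#' @param sex `"male"` or `"female"`.
#' @return A data frame of class `"kr_table"`.
#' @export
kr_table <- function(age, intercept, beta_stature, beta_weight,
                     beta_midparent, sex = c("male", "female")) {
  sex <- match.arg(sex)
  n <- length(age)
  if (n < 2L) stop("a coefficient table needs at least two age rows")
  lens <- c(length(intercept), length(beta_stature), length(beta_weight),
            length(beta_midparent))
  if (any(lens != n)) stop("all coefficient columns must match length(age)")
  if (any(diff(age) <= 0)) stop("coefficient ages must be strictly increasing")
  structure(data.frame(age = age, intercept = intercept,
                       beta_stature = beta_stature, beta_weight = beta_weight,
                       beta_midparent = beta_midparent),
            sex = sex, class = c("kr_table", "data.frame"))
}

#' Read Khamis-Roche-style coefficients from delimited text
#'
#' Expects header `sex,age_years,intercept,beta_stature,beta_weight,beta_midparent`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A list with one [kr_table()] per sex present in the file.
#' @export
read_kr_table <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sex", "age_years", "intercept", "beta_stature", "beta_weight",
            "beta_midparent")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("coefficient file is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (s in unique(d$sex)) {
    b <- d[d$sex == s, ]
    b <- b[order(b$age_years), ]
    out[[s]] <- kr_table(b$age_years, b$intercept, b$beta_stature,
                         b$beta_weight, b$beta_midparent, sex = s)
  }
  out
}

#' Predict adult height from current anthropometry
#'
#' Linear prediction with age-interpolated coefficients. The prediction is not
#' forced above the current stature: for extreme inputs the linear model can
#' predict below, in which case a warning is issued and the value returned
#' as-is.
#'
#' @param age Age(s) in decimal years, within the coefficient span.
#' @param stature Current stature (cm), positive.
#' @param weight Current weight (kg), positive.
#' @param midparent Mid-parent stature (cm) — the mean of the biological
#'   parents' statures — positive.
#' @param coeffs A [kr_table()] for the child's sex.
#' @return Predicted adult stature(s) in cm.
#' @export
predict_adult_height <- function(age, stature, weight, midparent, coeffs) {
  stopifnot(inherits(coeffs, "kr_table"))
  if (any(stature <= 0) || any(weight <= 0) || any(midparent <= 0))
    stop("stature, weight and mid-parent height must be positive")
  rng <- range(coeffs$age)
  if (any(age < rng[1] | age > rng[2]))
    stop(sprintf("age outside the coefficient span [%.2f, %.2f] years",
                 rng[1], rng[2]))
  a0 <- stats::approx(coeffs$age, coeffs$intercept, xout = age)$y
  b1 <- stats::approx(coeffs$age, coeffs$beta_stature, xout = age)$y
  b2 <- stats::approx(coeffs$age, coeffs$beta_weight, xout = age)$y
  b3 <- stats::approx(coeffs$age, coeffs$beta_midparent, xout = age)$y
  pred <- a0 + b1 * stature + b2 * weight + b3 * midparent
  low <- pred < stature - 1e-9
  if (any(low))
    warning(sprintf("%d prediction(s) below current stature", sum(low)))
  pred
}

#' Percent of predicted adult height attained
#'
#' `100 * current / predicted`. Values above 100 (child measured taller than
#' the prediction) are capped at 100 with a warning — the maturity scale ends
#' at full adult stature.
#'
#' @param current Current stature (cm), positive.
#' @param predicted Predicted adult stature (cm), positive.
#' @return Percent(s) in (0, 100].
#' @export
percent_adult_height <- function(current, predicted) {
  if (any(current <= 0)) stop("current stature must be positive")
  if (any(predicted <= 0)) stop("predicted adult stature must be positive")
  pct <- 100 * current / predicted
  over <- pct > 100
  if (any(over)) {
    warning(sprintf("%d percent-adult-height value(s) exceeded 100%%; capped",
                    sum(over)))
    pct[over] <- 100
  }
  pct
}

#' Biological age by inverse reference lookup
#'
#' Finds the age at which the reference mean percent of adult height equals
#' the attained percent, by monotone linear inverse interpolation on the
#' reference grid. Exact grid hits return the grid age; within a flat segment
#' of the reference the youngest age is returned. A percent outside the
#' reference's range raises an error reporting the boundary age it would clamp
#' to.
#'
#' @param percent Attained percent(s) of adult height.
#' @param reference A [build_pah_reference()] curve for the child's sex.
#' @return Biological age(s) in decimal years.
#' @export
biological_age <- function(percent, reference) {
  stopifnot(inherits(reference, "pah_reference"))
  p <- reference$percent
  a <- reference$age
  lo <- p[1]; hi <- p[length(p)]
  if (any(percent < lo))
    stop(sprintf(
      "percent below the reference minimum %.2f%%; would clamp to age %.2f",
      lo, a[1]))
  if (any(percent > hi))
    stop(sprintf(
      "percent above the reference maximum %.2f%%; would clamp to age %.2f",
      hi, a[length(a)]))
  # ties = min resolves flat reference segments to their youngest age
  stats::approx(p, a, xout = percent, ties = min)$y
}

#' Classify maturity timing from chronological and biological age
#'
#' Offset = biological age minus chronological age. A child whose biological
#' age is 1 year or more ahead is an early maturer; 1 year or more behind, a
#' late maturer; otherwise on time. The boundary (exactly +/- the threshold)
#' counts as early/late.
#'
#' @param chronological,biological Ages in decimal years, positive.
#' @param threshold Classification threshold in years (default 1).
#' @return A data frame with columns `offset` (years) and `timing` (factor
#'   `early` / `on_time` / `late`).
#' @export
classify_timing <- function(chronological, biological, threshold = 1) {
  if (any(chronological <= 0) || any(biological <= 0))
    stop("ages must be positive")
  if (threshold <= 0) stop("threshold must be positive")
  offset <- biological - chronological
  timing <- ifelse(offset >= threshold, "early",
                   ifelse(offset <= -threshold, "late", "on_time"))
  data.frame(offset = offset,
             timing = factor(timing, levels = c("early", "on_time", "late")))
}

#' Full maturity assessment for one or more children
#'
#' Chains [predict_adult_height()], [percent_adult_height()],
#' [biological_age()] and [classify_timing()].
#'
#' @inheritParams predict_adult_height
#' @inheritParams classify_timing
#' @param reference Percent-adult-height reference for the same sex as
#'   `coeffs`.
#' @return A data frame with columns `predicted_adult_height`,
#'   `percent_adult_height`, `biological_age`, `offset`, `timing`.
#' @export
assess_maturity <- function(age, stature, weight, midparent, coeffs,
                            reference, threshold = 1) {
  pred <- predict_adult_height(age, stature, weight, midparent, coeffs)
  pct <- percent_adult_height(stature, pred)
  bio <- biological_age(pct, reference)
  cls <- classify_timing(age, bio, threshold)
  data.frame(predicted_adult_height = pred, percent_adult_height = pct,
             biological_age = bio, offset = cls$offset, timing = cls$timing)
}
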