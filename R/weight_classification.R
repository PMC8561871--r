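# BMI, chronological vs biologically matched percentiles, category cut-offs,
# and the underweight exclusion used before modelling.

#' Body mass index
#'
#' @param weight Weight in kg, positive.
#' @param height Height in cm, positive.
#' @return BMI in kg/m^2.
#' @examples compute_bmi(50, 160)  # 19.53
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  weight / (height / 100)^2
}

#' BMI percentile against an age-matched LMS reference
#'
#' The matching age is chronological age for the standard classification, or
#' biological age for the maturity-adjusted classification (the child is
#' compared with reference peers at the same maturational stage rather than
#' the same calendar age). Optionally bins the matching age to the nearest
#' month before lookup, emulating month-resolution reference matching.
#'
#' @param bmi BMI value(s), kg/m^2.
#' @param matching_age Age(s) in decimal years used to index the reference.
#' @param bmi_reference An [lms_table()] with `measurement = "bmi"` for the
#'   child's sex.
#' @param month_binning If `TRUE`, round `matching_age` to the nearest month
#'   (1/12 year) before lookup.
#' @return Percentile(s) in (0, 100).
#' @export
bmi_percentile <- function(bmi, matching_age, bmi_reference,
                           month_binning = FALSE) {
  stopifnot(inherits(bmi_reference, "lms_table"))
  if (attr(bmi_reference, "measurement") != "bmi")
    stop("bmi_percentile requires a BMI reference table")
  if (isTRUE(month_binning)) matching_age <- round(matching_age * 12) / 12
  p <- lms_lookup(bmi_reference, matching_age)
  zscore_to_percentile(lms_zscore(bmi, p$L, p$M, p$S))
}

#' Weight-status category from a BMI percentile
#'
#' Cut-offs follow the screening convention: below the 2nd percentile is
#' underweight, 2nd up to (not including) the 85th is healthy weight, 85th up
#' to (not including) the 95th is overweight, and the 95th and above is
#' obese. Lower bounds are closed, upper bounds open.
#'
#' @param percentile Percentile(s) in (0, 100).
#' @param cutoffs Strictly increasing cut-offs
#'   `c(underweight, overweight, obese)`, default `c(2, 85, 95)`.
#' @return Factor with levels `underweight`, `healthy`, `overweight`, `obese`.
#' @export
bmi_category <- function(percentile, cutoffs = c(2, 85, 95)) {
  if (any(percentile <= 0) || any(percentile >= 100))
    stop("percentiles must lie strictly between 0 and 100")
  if (length(cutoffs) != 3L || any(diff(cutoffs) <= 0) ||
      cutoffs[1] <= 0 || cutoffs[3] >= 100)
    stop("cutoffs must be three strictly increasing values in (0, 100)")
  lev <- c("underweight", "healthy", "overweight", "obese")
  factor(lev[findInterval(percentile, cutoffs) + 1L], levels = lev)
}

#' Exclude children underweight at baseline from the modelling set
#'
#' Screening classifications retain underweight children descriptively, but
#' the modelling sample drops children who are underweight at visit 1 under
#' the chronological classification. Children who fall to underweight only
#' under the biological adjustment are retained and flagged.
#'
#' @param classified A data frame containing a `category_chronological_v1`
#'   factor (as produced by [classify_cohort()]).
#' @return The subset with underweight rows removed; the removed rows are
#'   attached as attribute `"excluded"` and flagged adjusted-only-underweight
#'   ids as attribute `"flagged_adjusted_underweight"`.
#' @export
exclude_underweight <- function(classified) {
  if (!"category_chronological_v1" %in% names(classified))
    stop("classified cohort must contain category_chronological_v1")
  uw <- classified$category_chronological_v1 == "underweight"
  out <- classified[!uw, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all children are underweight; the modelling set is empty")
  attr(out, "excluded") <- classified[uw, , drop = FALSE]
  if ("category_biological_v1" %in% names(classified)) {
    flg <- !uw & classified$category_biological_v1 == "underweight"
    attr(out, "flagged_adjusted_underweight") <-
      if ("id" %in% names(classified)) classified$id[flg] else which(flg)
  }
  out
}
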