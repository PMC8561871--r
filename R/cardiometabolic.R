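# Composite cardiometabolic risk: mean BP, mean arterial pressure,
# within-sample z-scores, CMR score and the high/low median split.

#' Mean of two successive blood-pressure readings
#'
#' @param r1,r2 Readings in mmHg, positive.
#' @return `(r1 + r2) / 2`.
#' @export
mean_bp <- function(r1, r2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("blood-pressure readings must be positive")
  (r1 + r2) / 2
}

#' Mean arterial pressure
#'
#' `MAP = (SBP + 2 * DBP) / 3`. Systolic below diastolic is physiologically
#' implausible and triggers a warning, not an error.
#'
#' @param sbp,dbp Systolic / diastolic pressure in mmHg, positive.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(sbp <= 0) || any(dbp <= 0)) stop("pressures must be positive")
  if (any(sbp < dbp))
    warning("systolic below diastolic for some readings; check input order")
  (sbp + 2 * dbp) / 3
}

# within-sample z-score (n-1 SD); errors if the component is degenerate
.zscore_within <- function(x, component) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop(sprintf("component '%s' has zero variance in this sample", component))
  (x - mean(x)) / s
}

#' Composite cardiometabolic risk score
#'
#' Sums within-sample z-scores of the reciprocal of HDL, LDL, fasting glucose
#' and mean arterial pressure: higher values mean higher risk (the HDL
#' reciprocal makes low protective-lipoprotein levels count upward). The
#' score is sample-specific: z-scores use the mean and (n-1) standard
#' deviation of the supplied analysis sample, optionally within strata (e.g.
#' sex).
#'
#' @param panel Data frame with columns `glucose`, `hdl`, `ldl` (mmol/L) and
#'   either `map` (mmHg) or the four readings `sbp1`, `sbp2`, `dbp1`, `dbp2`
#'   from which MAP is computed via [mean_bp()] and
#'   [mean_arterial_pressure()].
#' @param strata Optional factor of the same length as `nrow(panel)`;
#'   z-scores are computed within each stratum.
#' @return A data frame with `map`, the four z components (`z_inv_hdl`,
#'   `z_ldl`, `z_glucose`, `z_map`), `cmr`, and `risk` (factor `low`/`high`
#'   from [median_split()] of `cmr` within the whole sample).
#' @export
cmr_score <- function(panel, strata = NULL) {
  if (nrow(panel) < 2L) stop("CMR z-scores need a sample of at least 2")
  need <- c("glucose", "hdl", "ldl")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (any(panel$hdl <= 0)) stop("HDL must be strictly positive (reciprocal taken)")
  if (any(panel$glucose <= 0) || any(panel$ldl <= 0))
    stop("biomarker values must be positive")
  if ("map" %in% names(panel)) {
    map <- panel$map
  } else {
    bp <- c("sbp1", "sbp2", "dbp1", "dbp2")
    miss <- setdiff(bp, names(panel))
    if (length(miss))
      stop("panel needs either 'map' or columns: ", paste(bp, collapse = ", "))
    map <- mean_arterial_pressure(mean_bp(panel$sbp1, panel$sbp2),
                                  mean_bp(panel$dbp1, panel$dbp2))
  }
  comp <- data.frame(inv_hdl = 1 / panel$hdl, ldl = panel$ldl,
                     glucose = panel$glucose, map = map)
  zs <- if (is.null(strata)) {
    as.data.frame(lapply(names(comp), function(nm)
      .zscore_within(comp[[nm]], nm)))
  } else {
    strata <- as.factor(strata)
    if (length(strata) != nrow(panel))
      stop("strata must match the number of panel rows")
    out <- comp
    for (nm in names(comp)) {
      for (g in levels(strata)) {
        i <- strata == g
        if (sum(i) < 2L) stop("each stratum needs at least 2 children")
        out[[nm]][i] <- .zscore_within(comp[[nm]][i], nm)
      }
    }
    out
  }
  names(zs) <- c("z_inv_hdl", "z_ldl", "z_glucose", "z_map")
  cmr <- zs$z_inv_hdl + zs$z_ldl + zs$z_glucose + zs$z_map
  cbind(data.frame(map = map), zs,
        data.frame(cmr = cmr, risk = median_split(cmr)))
}

#' Median split into low / high risk
#'
#' Values strictly above the sample median are `high`; values at or below it
#' are `low` (ties at the median deterministically go low). A degenerate
#' sample with all values equal yields all-`low` with a warning.
#'
#' @param values Numeric vector, length at least 2.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("median split needs at least 2 values")
  if (length(unique(values)) == 1L)
    warning("all values equal; every child assigned to the low-risk half")
  med <- stats::median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}
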