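# Regression layer: transition tables with Pearson chi-square, multinomial
# logistic fits (via nnet) with AIC/BIC, deviance-dispersion scaling,
# model comparison and timing odds ratios.

#' Build a transition table from two classifications
#'
#' Cross-tabulates a baseline category against a follow-up category. Also
#' accepts a ready count matrix via `counts`.
#'
#' @param from,to Factors of equal length (ignored when `counts` is given).
#' @param counts Optional numeric matrix of non-negative cell counts, at
#'   least 2x2.
#' @return A count matrix of class `"transition_table"`.
#' @export
transition_table <- function(from = NULL, to = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(from) || is.null(to)) stop("supply (from, to) or counts")
    if (length(from) != length(to)) stop("from and to must have equal length")
    counts <- unclass(table(from = from, to = to))
  } else {
    counts <- as.matrix(counts)
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("a transition table must be at least 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  class(counts) <- c("transition_table", class(counts))
  counts
}

#' Pearson chi-square statistic of a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts `E = row total * column total /
#' grand total`, on `(r - 1)(c - 1)` degrees of freedom. All margins must be
#' positive.
#'
#' @param table A [transition_table()] or count matrix.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
pearson_chi2 <- function(table) {
  m <- unclass(as.matrix(table))
  r <- rowSums(m); c <- colSums(m)
  if (any(r == 0) || any(c == 0))
    stop("degenerate table: every row and column margin must be positive")
  E <- outer(r, c) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Row percentages of a transition table
#'
#' Each cell as a percent of its row total, rounded to `digits` for report
#' output (tables are conventionally printed as "count (row %)"). Rows with a
#' zero total return `NA`.
#'
#' @param table A [transition_table()] or count matrix.
#' @param digits Rounding digits (default 0, integer percents).
#' @return A matrix of percentages shaped like `table`.
#' @export
row_percentages <- function(table, digits = 0) {
  m <- unclass(as.matrix(table))
  rs <- rowSums(m)
  out <- 100 * sweep(m, 1, rs, "/")
  out[rs == 0, ] <- NA_real_
  round(out, digits)
}

#' @export
print.transition_table <- function(x, ...) {
  m <- unclass(as.matrix(x))
  pct <- row_percentages(m)
  cells <- matrix(sprintf("%d (%s%%)", m, ifelse(is.na(pct), "-", pct)),
                  nrow = nrow(m), dimnames = dimnames(m))
  for (i in seq_len(min(dim(m)))) cells[i, i] <- paste0("*", cells[i, i])
  cat("Transition table: count (row %), * marks same-category cells\n")
  print(cells, quote = FALSE)
  invisible(x)
}

#' Fit a multinomial logistic regression
#'
#' Maximum-likelihood multinomial logit via [nnet::multinom()], wrapped with
#' the bookkeeping used for model comparison: log-likelihood, deviance,
#' parameter count, AIC, `BIC = k * log(n) - 2 * logLik` (n = number of
#' children in the modelling sample), odds ratios with Wald confidence
#' intervals, and the percent of observations whose modal predicted category
#' matches the observed one. Non-convergence is an error, not a silent
#' result.
#'
#' @param formula Model formula; the response must be a factor (its first
#'   level, or `reference`, is the baseline contrast).
#' @param data Data frame; rows with missing modelling variables are an
#'   error — filter explicitly first.
#' @param reference Optional response level to use as the baseline.
#' @param label Specification label carried into reports.
#' @param maxit,reltol Optimiser control (defaults 500 iterations, relative
#'   deviance change 1e-12 — tight enough that coefficients are reproducible
#'   to well below 1e-6 against an independent fit).
#' @return An object of class `"cm_fit"`.
#' @export
fit_multinomial <- function(formula, data, reference = NULL,
                            label = deparse(formula), maxit = 500,
                            reltol = 1e-12) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("the outcome must have at least 2 observed levels")
  if (!is.null(reference)) {
    if (!reference %in% levels(y)) stop("reference level not found in outcome")
    y <- stats::relevel(y, ref = reference)
  }
  dat <- data.frame(.outcome = y, mf[, -1, drop = FALSE], check.names = FALSE)
  # empty predictor x outcome cells make coefficients inestimable; detect the
  # worst case (a factor level never observed with some outcome) up front
  for (v in names(dat)[-1]) {
    if (is.factor(dat[[v]]) || is.character(dat[[v]])) {
      tab <- table(dat[[v]], dat$.outcome)
      if (any(tab == 0))
        warning(sprintf(
          "empty cell(s) between predictor '%s' and the outcome; estimates may be unstable",
          v))
    }
  }
  f2 <- stats::reformulate(attr(stats::terms(mf), "term.labels"),
                           response = ".outcome")
  fit <- nnet::multinom(f2, data = dat, trace = FALSE, Hess = TRUE,
                        maxit = maxit, reltol = reltol)
  if (!is.null(fit$convergence) && fit$convergence != 0)
    stop("multinomial fit did not converge; check for separation or sparse cells")
  cf <- stats::coef(fit)
  lev <- levels(y)
  if (is.null(dim(cf)))
    cf <- matrix(cf, nrow = 1, dimnames = list(lev[2], names(cf)))
  v <- stats::vcov(fit)
  se <- matrix(sqrt(diag(v)), nrow = nrow(cf), byrow = TRUE,
               dimnames = dimnames(cf))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(cf)
  n <- nrow(dat)
  pred <- stats::predict(fit, type = "class")
  structure(list(
    label = label,
    formula = formula,
    outcome = as.character(formula[[2]]),
    levels = lev,
    reference = lev[1],
    coefficients = cf,
    se = se,
    dispersion = 1,
    scaled = FALSE,
    log_lik = ll,
    deviance = fit$deviance,
    df_residual = n * (nlevels(y) - 1L) - k,
    k = k,
    n = n,
    aic = 2 * k - 2 * ll,
    bic = k * log(n) - 2 * ll,
    percent_correct = 100 * mean(pred == y),
    fit = fit), class = "cm_fit")
}

#' @export
coef.cm_fit <- function(object, ...) object$coefficients

#' @export
logLik.cm_fit <- function(object, ...) {
  structure(object$log_lik, df = object$k, nobs = object$n, class = "logLik")
}

#' Odds ratios with Wald confidence intervals from a fit
#'
#' Uses the (possibly dispersion-scaled) standard errors.
#'
#' @param fit A `"cm_fit"`.
#' @param level Confidence level (default 0.95).
#' @return A data frame with contrast, term, `or`, `lower`, `upper`.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "cm_fit"))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  cf <- fit$coefficients; se <- fit$se
  data.frame(
    contrast = rep(rownames(cf), ncol(cf)),
    term = rep(colnames(cf), each = nrow(cf)),
    or = exp(as.vector(cf)),
    lower = exp(as.vector(cf) - zc * as.vector(se)),
    upper = exp(as.vector(cf) + zc * as.vector(se)))
}

#' Apply deviance-dispersion scaling to a fit
#'
#' Estimates the dispersion as `phi = deviance / residual df` and inflates
#' standard errors (hence confidence intervals) by `sqrt(phi)`. Coefficients,
#' log-likelihood, AIC and BIC are unchanged — scaling absorbs overdispersion
#' in inference, not in the information criteria.
#'
#' @param fit A `"cm_fit"`.
#' @return The fit with `se` scaled, `dispersion` set and `scaled = TRUE`.
#' @export
apply_dispersion_scaling <- function(fit) {
  stopifnot(inherits(fit, "cm_fit"))
  if (fit$df_residual <= 0) stop("no residual degrees of freedom")
  if (fit$scaled) return(fit)
  phi <- fit$deviance / fit$df_residual
  fit$se <- fit$se * sqrt(phi)
  fit$dispersion <- phi
  fit$scaled <- TRUE
  fit
}

#' Compare two fits of the same outcome by information criteria
#'
#' `delta_bic = BIC(b) - BIC(a)`; a magnitude below 2 is treated as
#' equivalent fit, otherwise the lower-BIC model is meaningfully better.
#'
#' @param fit_a,fit_b `"cm_fit"` objects for the same outcome and the same
#'   observation set.
#' @return A list of class `"model_comparison"` with `delta_aic`,
#'   `delta_bic`, `verdict` and `better` (label of the better model, or
#'   `NA` when equivalent).
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "cm_fit"), inherits(fit_b, "cm_fit"))
  if (fit_a$n != fit_b$n)
    stop("models were fitted to different numbers of observations")
  if (fit_a$outcome != fit_b$outcome)
    stop("models have different outcome variables")
  d_aic <- fit_b$aic - fit_a$aic
  d_bic <- fit_b$bic - fit_a$bic
  verdict <- if (abs(d_bic) < 2) "equivalent" else "meaningfully better"
  better <- if (verdict == "equivalent") NA_character_ else
    if (d_bic < 0) fit_b$label else fit_a$label
  structure(list(label_a = fit_a$label, label_b = fit_b$label,
                 delta_aic = d_aic, delta_bic = d_bic,
                 verdict = verdict, better = better),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: [%s] vs [%s]\n", x$label_a, x$label_b))
  cat(sprintf("  dAIC = %.2f, dBIC = %.2f -> %s%s\n", x$delta_aic, x$delta_bic,
              x$verdict,
              if (is.na(x$better)) "" else sprintf(" (%s)", x$better)))
  invisible(x)
}

#' @export
print.cm_fit <- function(x, ...) {
  cat(sprintf("Multinomial logit [%s]\n", x$label))
  cat(sprintf("  n = %d, k = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$n, x$k, x$log_lik, x$aic, x$bic))
  cat(sprintf("  dispersion phi = %.3f%s, correctly classified = %.1f%%\n",
              x$dispersion, if (x$scaled) " (SEs scaled)" else "",
              x$percent_correct))
  invisible(x)
}

#' @export
summary.cm_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients (log-odds vs reference '", object$reference, "'):\n",
      sep = "")
  print(round(object$coefficients, 4))
  cat("\nStandard errors:\n")
  print(round(object$se, 4))
  cat("\nOdds ratios:\n")
  or <- odds_ratios(object)
  or[c("or", "lower", "upper")] <- round(or[c("or", "lower", "upper")], 3)
  print(or, row.names = FALSE)
  invisible(object)
}

#' Odds of overweight/obesity by maturity-timing class
#'
#' 2x2 contingency odds ratio of an outcome (typically overweight-or-obese)
#' for early maturers versus everyone else, with a Woolf (log-normal)
#' confidence interval. Any zero cell triggers the Haldane-Anscombe
#' correction (0.5 added to every cell) with a warning.
#'
#' @param timing Factor with level `"early"` (as from [classify_timing()]).
#' @param outcome Logical vector: `TRUE` for the outcome of interest.
#' @param level Confidence level (default 0.95).
#' @return A list with `or`, `lower`, `upper`, and the 2x2 `table`
#'   (rows early/other, columns outcome/no-outcome).
#' @export
maturity_odds <- function(timing, outcome, level = 0.95) {
  if (length(timing) != length(outcome))
    stop("timing and outcome must have equal length")
  early <- timing == "early"
  a <- sum(early & outcome);  b <- sum(early & !outcome)
  c_ <- sum(!early & outcome); d <- sum(!early & !outcome)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("early", "other"), c("outcome", "none")))
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) {
    warning("zero cell in the 2x2 table; applying a 0.5 continuity correction")
    cells <- cells + 0.5
  }
  lor <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(lor), lower = exp(lor - zc * se), upper = exp(lor + zc * se),
       table = tab)
}
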