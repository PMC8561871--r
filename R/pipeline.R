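# End-to-end orchestration: schema checks, per-child classification under
# both matching schemes, exclusions, CMR scoring, transition tables, model
# fits and comparisons, and report output.

.COHORT_COLS <- c("id", "sex", "ethnicity", "ses", "age_v1", "height_v1",
                  "weight_v1", "age_v2", "height_v2", "weight_v2",
                  "mother_height", "father_height", "glucose", "hdl", "ldl",
                  "sbp1", "sbp2", "dbp1", "dbp2")

#' Analysis options for the classification pipeline
#'
#' @param cutoffs Percentile cut-offs `c(underweight, overweight, obese)`,
#'   strictly increasing in (0, 100); default `c(2, 85, 95)`.
#' @param timing_threshold Years of biological-chronological age discrepancy
#'   that defines early/late maturity (default 1).
#' @param cmr_sex_stratified If `TRUE`, CMR z-scores are computed within sex
#'   rather than pooled.
#' @param month_binning If `TRUE`, reference-matching ages are binned to the
#'   nearest month before percentile lookup.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cutoffs = c(2, 85, 95), timing_threshold = 1,
                            cmr_sex_stratified = FALSE,
                            month_binning = FALSE) {
  if (length(cutoffs) != 3L || any(diff(cutoffs) <= 0) ||
      cutoffs[1] <= 0 || cutoffs[3] >= 100)
    stop("cutoffs must be three strictly increasing percentiles in (0, 100)")
  if (timing_threshold <= 0) stop("timing_threshold must be positive")
  structure(list(cutoffs = cutoffs, timing_threshold = timing_threshold,
                 cmr_sex_stratified = isTRUE(cmr_sex_stratified),
                 month_binning = isTRUE(month_binning)),
            class = "pipeline_config")
}

# returns list(keep = logical, reasons = data.frame(id, reason))
.complete_case <- function(cohort) {
  reasons <- character(nrow(cohort))
  for (col in .COHORT_COLS) {
    bad <- is.na(cohort[[col]]) & reasons == ""
    reasons[bad] <- paste("missing", col)
  }
  list(keep = reasons == "",
       log = data.frame(id = cohort$id[reasons != ""],
                        reason = reasons[reasons != ""],
                        stringsAsFactors = FALSE))
}

#' Classify a cohort under chronological and biological matching
#'
#' For each child: BMI at both visits; maturity assessment at visit 1
#' (predicted adult height, percent attained, biological age, timing class);
#' BMI percentile and weight-status category at each visit matched to
#' chronological age and, separately, to biological age. Children with
#' missing modelling variables, or whose percent of adult height falls
#' outside the reference curve, are moved to the exclusion log rather than
#' classified. At the second visit, coefficient-table ages are clamped to
#' the table maximum (the prediction there equals attained stature) and
#' percent of adult height is capped at the 100% ceiling.
#'
#' @param cohort Data frame with the standard cohort schema (see
#'   [generate_cohort()]); missing columns are a schema error naming them.
#' @param refs A [synthetic_references()]-style reference set.
#' @param config A [pipeline_config()].
#' @return A data frame of class `"classified_cohort"`, one row per retained
#'   child, with attribute `"exclusions"` (a data frame of id + reason
#'   covering every dropped child).
#' @export
classify_cohort <- function(cohort, refs = synthetic_references(),
                            config = pipeline_config()) {
  stopifnot(inherits(refs, "growth_refs"))
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  miss <- setdiff(.COHORT_COLS, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  bad_sex <- !cohort$sex %in% c("male", "female")
  if (any(bad_sex)) stop("sex must be 'male' or 'female'")

  cc <- .complete_case(cohort)
  excl <- cc$log
  d <- cohort[cc$keep, , drop = FALSE]

  d$midparent <- (d$mother_height + d$father_height) / 2
  d$bmi_v1 <- compute_bmi(d$weight_v1, d$height_v1)
  d$bmi_v2 <- compute_bmi(d$weight_v2, d$height_v2)

  out <- vector("list", 2)
  names(out) <- c("male", "female")
  for (s in c("male", "female")) {
    i <- d$sex == s
    if (!any(i)) next
    ds <- d[i, , drop = FALSE]
    kr <- refs$kr[[s]]; pah <- refs$pah[[s]]; bref <- refs$bmi[[s]]
    kr_max <- max(kr$age)

    pred1 <- predict_adult_height(pmin(ds$age_v1, kr_max), ds$height_v1,
                                  ds$weight_v1, ds$midparent, kr)
    pct1 <- percent_adult_height(ds$height_v1, pred1)
    in_range <- pct1 >= min(pah$percent) & pct1 <= max(pah$percent)
    if (any(!in_range)) {
      excl <- rbind(excl, data.frame(
        id = ds$id[!in_range],
        reason = "percent of adult height outside the reference curve",
        stringsAsFactors = FALSE))
      ds <- ds[in_range, , drop = FALSE]
      pred1 <- pred1[in_range]; pct1 <- pct1[in_range]
    }
    if (!nrow(ds)) next
    bio1 <- biological_age(pct1, pah)
    tim <- classify_timing(ds$age_v1, bio1, config$timing_threshold)

    # visit 2: near adult stature; cap the maturity ratio at its ceiling
    pred2 <- suppressWarnings(
      predict_adult_height(pmin(ds$age_v2, kr_max), ds$height_v2,
                           ds$weight_v2, ds$midparent, kr))
    pct2 <- suppressWarnings(percent_adult_height(ds$height_v2, pred2))
    pct2 <- pmax(pct2, min(pah$percent))
    bio2 <- biological_age(pct2, pah)

    p_c1 <- bmi_percentile(ds$bmi_v1, ds$age_v1, bref, config$month_binning)
    p_b1 <- bmi_percentile(ds$bmi_v1, bio1, bref, config$month_binning)
    p_c2 <- bmi_percentile(ds$bmi_v2, pmin(ds$age_v2, max(bref$age)), bref,
                           config$month_binning)
    p_b2 <- bmi_percentile(ds$bmi_v2, bio2, bref, config$month_binning)

    out[[s]] <- data.frame(
      id = ds$id, sex = ds$sex, ethnicity = ds$ethnicity, ses = ds$ses,
      age_v1 = ds$age_v1, age_v2 = ds$age_v2,
      bmi_v1 = ds$bmi_v1, bmi_v2 = ds$bmi_v2,
      predicted_adult_height = pred1, percent_adult_height = pct1,
      biological_age = bio1, offset = tim$offset, timing = tim$timing,
      percentile_chronological_v1 = p_c1, percentile_biological_v1 = p_b1,
      percentile_chronological_v2 = p_c2, percentile_biological_v2 = p_b2,
      category_chronological_v1 = bmi_category(p_c1, config$cutoffs),
      category_biological_v1 = bmi_category(p_b1, config$cutoffs),
      category_chronological_v2 = bmi_category(p_c2, config$cutoffs),
      category_biological_v2 = bmi_category(p_b2, config$cutoffs),
      glucose = ds$glucose, hdl = ds$hdl, ldl = ds$ldl,
      sbp1 = ds$sbp1, sbp2 = ds$sbp2, dbp1 = ds$dbp1, dbp2 = ds$dbp2,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(match(res$id, cohort$id)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "exclusions") <- excl
  class(res) <- c("classified_cohort", class(res))
  res
}

.cat_score <- function(category) {
  # ordinal score: healthy (and below) = 0, overweight = 1, obese = 2
  pmax(as.integer(category) - 2L, 0L)
}

# covariate terms that actually vary in this sample
.varying <- function(data, candidates) {
  candidates[vapply(candidates,
                    function(v) length(unique(data[[v]])) > 1L, logical(1))]
}

#' Run the full maturity-adjusted weight-status analysis
#'
#' Classifies the cohort under both matching schemes ([classify_cohort()]),
#' removes children underweight at baseline ([exclude_underweight()]),
#' scores the cardiometabolic panel ([cmr_score()]), builds visit-1 to
#' visit-2 transition tables with Pearson chi-square for each scheme, fits
#' multinomial logistic models predicting (a) visit-2 BMI category and
#' (b) high cardiometabolic risk from the visit-1 category score (ordinal:
#' healthy 0, overweight 1, obese 2) plus sex, ethnicity and SES under each
#' scheme, applies deviance-dispersion scaling, compares each pair by
#' AIC/BIC, fits the interaction models (timing x category score and timing
#' x sex, covariates dropped for parsimony), and computes timing odds ratios
#' and reclassification summaries.
#'
#' @inheritParams classify_cohort
#' @return A list of class `"maturity_analysis"`; see the package vignette
#'   for the layout of its components.
#' @export
analyse_cohort <- function(cohort, refs = synthetic_references(),
                           config = pipeline_config()) {
  classified <- classify_cohort(cohort, refs, config)
  modelling <- exclude_underweight(classified)
  excl <- attr(classified, "exclusions")
  uw <- attr(modelling, "excluded")
  if (nrow(uw))
    excl <- rbind(excl, data.frame(id = uw$id,
                                   reason = "underweight at visit 1",
                                   stringsAsFactors = FALSE))
  if (nrow(modelling) < 10L)
    stop("modelling sample too small after exclusions")

  cmr <- cmr_score(modelling,
                   strata = if (config$cmr_sex_stratified) modelling$sex)
  modelling$cmr <- cmr$cmr
  modelling$risk <- cmr$risk
  modelling$score_chronological <-
    .cat_score(modelling$category_chronological_v1)
  modelling$score_biological <- .cat_score(modelling$category_biological_v1)

  descriptives <- .describe(classified, modelling)

  three <- c("healthy", "overweight", "obese")
  tr <- list()
  for (scheme in c("chronological", "biological")) {
    v1 <- modelling[[paste0("category_", scheme, "_v1")]]
    v2 <- modelling[[paste0("category_", scheme, "_v2")]]
    keep <- v1 %in% three & v2 %in% three
    tab <- transition_table(factor(as.character(v1[keep]), levels = three),
                            factor(as.character(v2[keep]), levels = three))
    tr[[scheme]] <- list(table = tab, chi2 = pearson_chi2(tab),
                         row_pct = row_percentages(tab))
  }

  # weight-status models share one outcome (the age-17 category, at which
  # age the maturity adjustment is negligible) and one observation set;
  # only the visit-1 predictor scheme differs, so AIC/BIC are comparable
  m <- modelling
  ok_a <- m$category_chronological_v2 %in% three
  da <- m[ok_a, , drop = FALSE]
  da$weight_v2 <- factor(as.character(da$category_chronological_v2),
                         levels = three)
  covar <- .varying(da, c("sex", "ethnicity", "ses"))

  fits <- list(
    weight_chronological = apply_dispersion_scaling(fit_multinomial(
      stats::reformulate(c("score_chronological", covar), "weight_v2"),
      da, reference = "healthy", label = "weight status ~ chronological categories")),
    weight_biological = apply_dispersion_scaling(fit_multinomial(
      stats::reformulate(c("score_biological", covar), "weight_v2"),
      da, reference = "healthy", label = "weight status ~ biological categories")),
    cmr_chronological = apply_dispersion_scaling(fit_multinomial(
      stats::reformulate(c("score_chronological", covar), "risk"),
      m, reference = "low", label = "CMR ~ chronological categories")),
    cmr_biological = apply_dispersion_scaling(fit_multinomial(
      stats::reformulate(c("score_biological", covar), "risk"),
      m, reference = "low", label = "CMR ~ biological categories")))

  comparisons <- list(
    weight = compare_models(fits$weight_chronological,
                            fits$weight_biological),
    cmr = compare_models(fits$cmr_chronological, fits$cmr_biological))

  interactions <- list()
  if (nlevels(droplevels(m$timing)) > 1L) {
    m$timing <- droplevels(m$timing)
    da$timing <- droplevels(da$timing)
    interactions$weight <- apply_dispersion_scaling(fit_multinomial(
      weight_v2 ~ score_biological * timing + sex * timing, da,
      reference = "healthy",
      label = "weight status ~ biological categories x timing + sex x timing"))
    interactions$cmr <- apply_dispersion_scaling(fit_multinomial(
      risk ~ score_biological * timing + sex * timing, m,
      reference = "low",
      label = "CMR ~ biological categories x timing + sex x timing"))
  }

  owob <- m$category_chronological_v1 %in% c("overweight", "obese")
  odds <- list(
    overweight_obese = maturity_odds(m$timing, owob),
    obese = maturity_odds(m$timing, m$category_chronological_v1 == "obese"))

  reclass <- .reclassification(m)

  structure(list(descriptives = descriptives, transitions = tr, fits = fits,
                 comparisons = comparisons, interactions = interactions,
                 odds = odds, reclassification = reclass,
                 classified = classified, modelling = m,
                 exclusions = excl, config = config),
            class = "maturity_analysis")
}

.describe <- function(classified, modelling) {
  by_sex <- function(f) {
    c(male = f(classified[classified$sex == "male", , drop = FALSE]),
      female = f(classified[classified$sex == "female", , drop = FALSE]),
      all = f(classified))
  }
  cat_tab <- function(col) {
    t(vapply(c("male", "female"), function(s)
      table(classified[[col]][classified$sex == s]),
      numeric(4)))
  }
  list(
    n = nrow(classified),
    n_modelling = nrow(modelling),
    n_by_sex = table(classified$sex),
    age_v1 = by_sex(function(d) mean(d$age_v1)),
    bmi_v1 = by_sex(function(d) mean(d$bmi_v1)),
    percent_adult_height = by_sex(function(d) mean(d$percent_adult_height)),
    categories_chronological = cat_tab("category_chronological_v1"),
    categories_biological = cat_tab("category_biological_v1"),
    timing = t(vapply(c("male", "female"), function(s)
      table(classified$timing[classified$sex == s]), numeric(3))))
}

.reclassification <- function(m) {
  owob <- m$category_chronological_v1 %in% c("overweight", "obese")
  down <- as.integer(m$category_biological_v1) <
    as.integer(m$category_chronological_v1)
  pct <- function(i) if (sum(i) == 0) NA_real_ else 100 * mean(down[i])
  list(percent_down_overall = pct(owob),
       percent_down_boys = pct(owob & m$sex == "male"),
       percent_down_girls = pct(owob & m$sex == "female"))
}

#' @export
print.maturity_analysis <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf("Maturity-adjusted weight-status analysis: %d children (%d modelled)\n",
              d$n, d$n_modelling))
  tt <- colSums(d$timing)
  cat(sprintf("  timing: %d early / %d on-time / %d late\n",
              tt[1], tt[2], tt[3]))
  r <- x$reclassification
  cat(sprintf("  moved down a category by adjustment (of overweight/obese): %.0f%% (boys %.0f%%, girls %.0f%%)\n",
              r$percent_down_overall, r$percent_down_boys, r$percent_down_girls))
  for (s in names(x$transitions))
    cat(sprintf("  %s transition chi2 = %.1f (df %d)\n", s,
                x$transitions[[s]]$chi2$statistic, x$transitions[[s]]$chi2$df))
  cat(sprintf("  weight-status models: dBIC (bio - chron) = %.2f [%s]\n",
              x$comparisons$weight$delta_bic, x$comparisons$weight$verdict))
  cat(sprintf("  CMR models:           dBIC (bio - chron) = %.2f [%s]\n",
              x$comparisons$cmr$delta_bic, x$comparisons$cmr$verdict))
  o <- x$odds$overweight_obese
  cat(sprintf("  early-maturer OR for overweight/obesity: %.2f (%.2f-%.2f)\n",
              o$or, o$lower, o$upper))
  invisible(x)
}

#' @export
summary.maturity_analysis <- function(object, ...) {
  print(object)
  cat("\nBMI categories at visit 1 (chronological matching):\n")
  print(object$descriptives$categories_chronological)
  cat("\nBMI categories at visit 1 (biological matching):\n")
  print(object$descriptives$categories_biological)
  for (s in names(object$transitions)) {
    cat(sprintf("\nTransition table (%s):\n", s))
    print(object$transitions[[s]]$table)
  }
  cat("\nModel fits:\n")
  for (f in object$fits) print(f)
  invisible(object)
}

#' Run the pipeline end to end and write a report bundle
#'
#' Orchestrates [analyse_cohort()] and writes: descriptive tables for both
#' classification schemes, transition tables with chi-square statistics,
#' model-fit summaries and odds ratios as delimited text, a machine-readable
#' `results.json`, and a run log echoing the configuration and seed. All
#' content is computed before anything is written, so a failed run leaves no
#' partial output.
#'
#' @param cohort A cohort data frame or a path to a delimited cohort file.
#' @param out_dir Output directory (created if needed).
#' @inheritParams classify_cohort
#' @param seed Optional integer; recorded in the outputs and set before
#'   analysis so any stochastic steps are reproducible.
#' @return The `"maturity_analysis"` object, invisibly, with attribute
#'   `"paths"` naming the files written.
#' @export
run_pipeline <- function(cohort, out_dir, refs = synthetic_references(),
                         config = pipeline_config(), seed = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!is.null(seed)) set.seed(seed)
  an <- analyse_cohort(cohort, refs, config)

  desc_txt <- utils::capture.output(summary(an))
  fits_all <- c(an$fits, an$interactions)
  fit_df <- do.call(rbind, lapply(fits_all, function(f)
    data.frame(label = f$label, n = f$n, k = f$k, log_lik = f$log_lik,
               deviance = f$deviance, dispersion = f$dispersion,
               aic = f$aic, bic = f$bic,
               percent_correct = f$percent_correct)))
  or_df <- do.call(rbind, lapply(fits_all, function(f)
    cbind(label = f$label, odds_ratios(f))))
  results <- list(
    n = an$descriptives$n,
    n_modelling = an$descriptives$n_modelling,
    n_excluded = nrow(an$exclusions),
    seed = seed,
    config = unclass(an$config),
    timing_counts = as.list(colSums(an$descriptives$timing)),
    chi2 = lapply(an$transitions, function(t)
      t$chi2[c("statistic", "df")]),
    delta_bic = list(weight = an$comparisons$weight$delta_bic,
                     cmr = an$comparisons$cmr$delta_bic),
    verdicts = list(weight = an$comparisons$weight$verdict,
                    cmr = an$comparisons$cmr$verdict),
    odds = list(overweight_obese = an$odds$overweight_obese$or,
                obese = an$odds$obese$or),
    reclassification = an$reclassification)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(report = file.path(out_dir, "report.txt"),
             fits = file.path(out_dir, "model_fits.csv"),
             odds = file.path(out_dir, "odds_ratios.csv"),
             results = file.path(out_dir, "results.json"),
             log = file.path(out_dir, "run.log"),
             exclusions = file.path(out_dir, "exclusions.csv"))
  writeLines(desc_txt, paths["report"])
  utils::write.csv(fit_df, paths["fits"], row.names = FALSE)
  utils::write.csv(or_df, paths["odds"], row.names = FALSE)
  jsonlite::write_json(results, paths["results"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c("maturity-adjusted weight-status pipeline",
               sprintf("seed: %s", if (is.null(seed)) "none" else seed),
               sprintf("children in: %d; modelled: %d; excluded: %d",
                       nrow(cohort), an$descriptives$n_modelling,
                       nrow(an$exclusions)),
               "config:",
               utils::capture.output(utils::str(unclass(config)))),
             paths["log"])
  utils::write.csv(an$exclusions, paths["exclusions"], row.names = FALSE)
  attr(an, "paths") <- paths
  invisible(an)
}
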