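# Seeded synthetic-cohort generator. Emulates the variables a maturity-
# adjusted weight-status analysis needs (two anthropometric visits, parental
# statures, demographics, a fasting cardiometabolic panel) and carries latent
# truths so pipeline estimates can be validated against known values.

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate a UK birth-cohort follow-up: 1525 children measured at
#' about 11.75 and 17.71 years, roughly 20% early / 76% on-time / 4% late
#' maturers overall (32%/5% early/late in girls, 8%/2% in boys), and
#' baseline weight-status prevalences of about 2% underweight / 75% healthy /
#' 11% overweight / 12% obese under chronological norms.
#'
#' The maturity-offset distribution is parameterised by the per-sex early and
#' late shares: the generator solves for the normal mean and SD such that
#' P(offset >= +1) and P(offset <= -1) equal the configured shares (both
#' zero yields a degenerate all-on-time cohort). `bmi_inflation` is the
#' transient extra BMI carried per year of maturity offset (kg/m^2 per year);
#' `NULL` resolves it to the reference median BMI gradient at the baseline
#' age, which makes the biologically matched percentile recover a child's
#' underlying adiposity. `early_adiposity_shift` is persistent extra
#' adiposity (in z-units) for early maturers and propagates to the second
#' visit through `tracking_rho`.
#'
#' @param n Number of children (>= 2).
#' @param prop_female Proportion female.
#' @param prop_white Proportion of the `white` ethnicity level.
#' @param ses_probs Named probabilities over the four maternal SES groups.
#' @param age_v1,age_v2 `c(mean, sd)` of visit ages in years.
#' @param timing_props List with `male` / `female` elements, each
#'   `c(early = , late = )` shares in [0, 1) with sum < 1.
#' @param bmi_z_mean,bmi_z_sd Mean and SD of the underlying adiposity
#'   z-score relative to the BMI reference (defaults give the prevalences
#'   above once the maturity channels are added).
#' @param bmi_z_skew Right-skew of the adiposity distribution: the standard
#'   draw is a standardized lognormal with log-scale SD `bmi_z_skew`
#'   (0 recovers a normal). Cohorts heavier than their reference population
#'   show such right-skewed z-distributions.
#' @param bmi_inflation kg/m^2 of transient (median) BMI per year of
#'   maturity offset, or `NULL` for the reference gradient. Internally the
#'   coefficient displaces the child's whole BMI distribution along the
#'   reference age axis by `offset * bmi_inflation / gradient` years, so at
#'   the default a maturity-advanced child's BMI is distributed like that of
#'   the reference group at their biological age (spread and skew included,
#'   not just the median).
#' @param early_adiposity_shift Persistent adiposity shift (z-units) for
#'   early maturers.
#' @param tracking_rho Correlation between underlying adiposity at the two
#'   visits, in [-1, 1].
#' @param cmr_effects Named vector `c(bmi_step, male, early)`: latent-risk
#'   increments per age-17 BMI-category step, for boys, and for early
#'   maturers (risk units; the latent risk has unit residual SD).
#' @param noise Named vector `c(height, weight)`: measurement noise SDs in
#'   cm and kg added to true anthropometry.
#' @param parent_height_sd Population SD of parental statures (cm).
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 1525,
                          prop_female = 0.516,
                          prop_white = 0.98,
                          ses_probs = c(professional = 0.33,
                                        intermediate = 0.18,
                                        junior_nonmanual = 0.27,
                                        manual = 0.22),
                          age_v1 = c(mean = 11.75, sd = 0.20),
                          age_v2 = c(mean = 17.71, sd = 0.36),
                          timing_props = list(
                            male = c(early = 0.08, late = 0.02),
                            female = c(early = 0.32, late = 0.05)),
                          bmi_z_mean = -0.03,
                          bmi_z_sd = 1.25,
                          bmi_z_skew = 0.30,
                          bmi_inflation = NULL,
                          early_adiposity_shift = 0.80,
                          tracking_rho = 0.85,
                          cmr_effects = c(bmi_step = 0.8, male = 0.5,
                                          early = 0.4),
                          noise = c(height = 0.3, weight = 0.3),
                          parent_height_sd = 6.5) {
  if (n < 2) stop("n must be at least 2")
  if (prop_female < 0 || prop_female > 1 || prop_white < 0 || prop_white > 1)
    stop("proportions must lie in [0, 1]")
  if (abs(sum(ses_probs) - 1) > 1e-8) stop("ses_probs must sum to 1")
  if (any(ses_probs < 0)) stop("ses_probs must be non-negative")
  for (s in c("male", "female")) {
    tp <- timing_props[[s]]
    if (is.null(tp) || !all(c("early", "late") %in% names(tp)))
      stop("timing_props must give early and late shares for each sex")
    if (any(tp < 0) || sum(tp) >= 1)
      stop("per-sex early + late shares must be non-negative and sum below 1")
    if (xor(tp["early"] == 0, tp["late"] == 0))
      stop("early and late shares must be both zero (degenerate) or both positive")
  }
  if (abs(tracking_rho) > 1) stop("tracking_rho must lie in [-1, 1]")
  if (bmi_z_sd <= 0) stop("bmi_z_sd must be positive")
  if (bmi_z_skew < 0) stop("bmi_z_skew must be non-negative")
  if (any(noise < 0) || parent_height_sd < 0)
    stop("noise SDs must be non-negative")
  if (age_v1["sd"] < 0 || age_v2["sd"] < 0) stop("age SDs must be non-negative")
  structure(as.list(environment()), class = "cohort_config")
}

# standardized lognormal: mean 0, SD 1, right skew growing with tau
.skew_std <- function(z, tau) {
  if (tau == 0) return(z)
  (exp(tau * z) - exp(tau^2 / 2)) /
    sqrt((exp(tau^2) - 1) * exp(tau^2))
}

# normal (mu, sd) with P(X >= 1) = p_early and P(X <= -1) = p_late
.solve_offset_dist <- function(p_early, p_late) {
  p_early <- unname(p_early); p_late <- unname(p_late)
  if (p_early == 0 && p_late == 0) return(c(mu = 0, sd = 0))
  q1 <- stats::qnorm(1 - p_early)
  q2 <- stats::qnorm(p_late)
  sd <- 2 / (q1 - q2)
  c(mu = 1 - sd * q1, sd = sd)
}

# child height consistent with attaining `pct`% of the coefficient-table
# prediction, given BMI and mid-parent height: solves
# h = (pct/100) * (a0 + b1 h + b2 * bmi (h/100)^2 + b3 mp)
# exactly (quadratic in h; the smaller root is the physical one and tends to
# the linear solution as the weight term vanishes)
.solve_height <- function(pct, bmi, midparent, a0, b1, b2, b3) {
  f <- pct / 100
  A <- f * b2 * bmi / 1e4
  B <- f * b1 - 1
  C <- f * (a0 + b3 * midparent)
  disc <- B^2 - 4 * A * C
  if (any(disc < 0))
    stop("infeasible config: no consistent stature for some children")
  lin <- -C / B
  quad <- (-B - sqrt(disc)) / (2 * A)
  h <- ifelse(abs(A) < 1e-12, lin, quad)
  if (any(!is.finite(h)) || any(h <= 0))
    stop("infeasible config: no consistent stature for some children")
  h
}

#' Generate a seeded synthetic cohort
#'
#' Draws demographics, visit ages, a latent maturity offset per child
#' (biological minus chronological age), parental statures, an underlying
#' adiposity z-score, and constructs anthropometry so the pipeline can
#' recover the latent structure: visit-1 height is solved to be exactly the
#' latent percent of the (coefficient-table) predicted adult height implied
#' by the child's biological age, and visit-1 BMI is the reference value of
#' the adiposity z-score at chronological age plus the transient maturity
#' inflation. Visit-2 BMI tracks underlying adiposity with correlation
#' `tracking_rho`; the fasting panel is generated from a latent risk driven
#' by visit-2 BMI category, sex and early timing. With zero measurement
#' noise, pipeline-estimated biological age equals the latent value up to
#' interpolation error.
#'
#' @param config A [cohort_config()].
#' @param refs A [synthetic_references()]-style reference set.
#' @param seed Optional integer seed; identical (config, refs, seed) yield
#'   byte-identical output.
#' @return A list of class `"synthetic_cohort"` with elements `cohort` (the
#'   observable table, one row per child), `truth` (latent values: offset,
#'   percent of adult height, adult height, adiposity, timing class, latent
#'   risk) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            refs = synthetic_references(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(refs, "growth_refs"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  ethnicity <- ifelse(stats::runif(n) < config$prop_white, "white", "non_white")
  ses <- sample(names(config$ses_probs), n, replace = TRUE,
                prob = config$ses_probs)
  age_v1 <- stats::rnorm(n, config$age_v1["mean"], config$age_v1["sd"])
  age_v2 <- stats::rnorm(n, config$age_v2["mean"], config$age_v2["sd"])

  offset <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    d <- .solve_offset_dist(config$timing_props[[s]]["early"],
                            config$timing_props[[s]]["late"])
    offset[i] <- stats::rnorm(sum(i), d["mu"], d["sd"])
  }
  bio_v1 <- age_v1 + offset
  for (s in c("male", "female")) {
    rng <- range(refs$pah[[s]]$age)
    i <- sex == s
    if (any(bio_v1[i] < rng[1] | bio_v1[i] > rng[2]))
      stop("infeasible config: simulated biological ages fall outside the reference span")
  }

  mother_height <- stats::rnorm(n, refs$norms$female, config$parent_height_sd)
  father_height <- stats::rnorm(n, refs$norms$male, config$parent_height_sd)
  midparent <- (mother_height + father_height) / 2

  early_latent <- offset >= 1
  adiposity <- config$bmi_z_mean +
    config$bmi_z_sd * .skew_std(stats::rnorm(n), config$bmi_z_skew) +
    config$early_adiposity_shift * early_latent
  # cap extreme draws: no child above 3x the reference median BMI (also
  # keeps z well inside the Box-Cox support of each sex's reference)
  z_cap <- numeric(n)
  for (s in c("male", "female")) {
    L <- refs$bmi[[s]]$L[1]; S <- refs$bmi[[s]]$S[1]
    z_cap[sex == s] <- min(4.4, lms_zscore(3, L, 1, S))
  }
  adiposity <- pmin(pmax(adiposity, -4.4), z_cap)

  pct_v1 <- bmi_v1 <- height_v1 <- infl <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    bref <- refs$bmi[[s]]
    a0c <- unname(config$age_v1["mean"])
    grad <- (lms_lookup(bref, a0c + 0.5)$M -
               lms_lookup(bref, a0c - 0.5)$M)  # kg/m^2 per year at baseline
    lam <- config$bmi_inflation
    if (is.null(lam)) lam <- grad
    infl[i] <- lam
    # inflation displaces the whole BMI distribution along the age axis:
    # lam kg/m^2 (of median BMI) per offset year = lam/grad years of
    # reference age; at the default lam the child's BMI is distributed as
    # that of the reference group at their biological age
    age_eff <- age_v1[i] + (lam / grad) * offset[i]
    age_eff <- pmin(pmax(age_eff, min(bref$age)), max(bref$age))
    bmi_v1[i] <- lms_value(bref, age_eff, adiposity[i])
    if (any(bmi_v1[i] <= 10))
      stop("infeasible config: inflation drives BMI to implausible values")
    pct_v1[i] <- pah_at_age(refs$pah[[s]], bio_v1[i])
    kr <- refs$kr[[s]]
    a0 <- stats::approx(kr$age, kr$intercept, xout = age_v1[i])$y
    b1 <- stats::approx(kr$age, kr$beta_stature, xout = age_v1[i])$y
    b2 <- stats::approx(kr$age, kr$beta_weight, xout = age_v1[i])$y
    b3 <- stats::approx(kr$age, kr$beta_midparent, xout = age_v1[i])$y
    height_v1[i] <- .solve_height(pct_v1[i], bmi_v1[i], midparent[i],
                                  a0, b1, b2, b3)
  }
  weight_v1 <- bmi_v1 * (height_v1 / 100)^2
  adult_height <- height_v1 / (pct_v1 / 100)

  # visit 2: adiposity tracks, maturity gap has closed
  rho <- config$tracking_rho
  z_std <- (adiposity - config$bmi_z_mean) / config$bmi_z_sd
  z_v2 <- config$bmi_z_mean + config$bmi_z_sd *
    (rho * z_std + sqrt(1 - rho^2) * stats::rnorm(n))
  z_v2 <- pmin(pmax(z_v2, -4.4), z_cap)
  bmi_v2 <- height_v2 <- pct2 <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    bmi_v2[i] <- lms_value(refs$bmi[[s]], age_v2[i], z_v2[i])
    height_v2[i] <- adult_height[i] *
      pah_at_age(refs$pah[[s]], age_v2[i]) / 100
    pct2[i] <- zscore_to_percentile(z_v2[i])
  }
  weight_v2 <- bmi_v2 * (height_v2 / 100)^2

  # fasting panel from a latent risk score
  step_v2 <- findInterval(pct2, c(85, 95))  # 0 healthy, 1 overweight, 2 obese
  ef <- config$cmr_effects
  risk <- ef["bmi_step"] * step_v2 + ef["male"] * (sex == "male") +
    ef["early"] * early_latent + stats::rnorm(n)
  glucose <- pmax(5.2 + 0.10 * risk + stats::rnorm(n, 0, 0.35), 2.5)
  hdl <- pmax(1.40 - 0.06 * risk + stats::rnorm(n, 0, 0.22), 0.4)
  ldl <- pmax(2.25 + 0.15 * risk + stats::rnorm(n, 0, 0.55), 0.5)
  map_t <- 83 + 2.0 * risk + stats::rnorm(n, 0, 4.5)
  pulse <- pmax(stats::rnorm(n, 45, 7), 20)
  dbp <- map_t - pulse / 3
  sbp <- dbp + pulse

  nh <- config$noise["height"]; nw <- config$noise["weight"]
  cohort <- data.frame(
    id = sprintf("C%05d", seq_len(n)),
    sex = sex, ethnicity = ethnicity, ses = ses,
    age_v1 = age_v1,
    height_v1 = height_v1 + stats::rnorm(n, 0, nh),
    weight_v1 = pmax(weight_v1 + stats::rnorm(n, 0, nw), 5),
    age_v2 = age_v2,
    height_v2 = height_v2 + stats::rnorm(n, 0, nh),
    weight_v2 = pmax(weight_v2 + stats::rnorm(n, 0, nw), 20),
    mother_height = mother_height, father_height = father_height,
    glucose = glucose, hdl = hdl, ldl = ldl,
    sbp1 = sbp + stats::rnorm(n, 0, 2), sbp2 = sbp + stats::rnorm(n, 0, 2),
    dbp1 = dbp + stats::rnorm(n, 0, 2), dbp2 = dbp + stats::rnorm(n, 0, 2),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    id = cohort$id,
    offset = offset,
    percent_adult_height = pct_v1,
    adult_height = adult_height,
    adiposity = adiposity,
    timing = factor(ifelse(offset >= 1, "early",
                           ifelse(offset <= -1, "late", "on_time")),
                    levels = c("early", "on_time", "late")),
    bmi_inflation = infl,
    latent_risk = risk,
    stringsAsFactors = FALSE)
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tt <- table(x$truth$timing)
  cat(sprintf("Synthetic cohort: %d children (%.0f%% female)\n",
              nrow(x$cohort), 100 * mean(x$cohort$sex == "female")))
  cat(sprintf("  latent timing: %d early / %d on-time / %d late\n",
              tt["early"], tt["on_time"], tt["late"]))
  invisible(x)
}

#' Write a synthetic cohort to delimited text
#'
#' Writes the observable cohort table to `path` and the latent-truth table
#' to a sibling file with suffix `_truth`.
#'
#' @param x A [generate_cohort()] result.
#' @param path Output path for the cohort table (CSV).
#' @return Paths of the two files written, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "synthetic_cohort"))
  utils::write.csv(x$cohort, path, row.names = FALSE, quote = FALSE)
  tpath <- sub("(\\.[^.]+)?$", "_truth\\1", path)
  if (tpath == path) tpath <- paste0(path, "_truth")
  utils::write.csv(x$truth, tpath, row.names = FALSE, quote = FALSE)
  invisible(c(cohort = path, truth = tpath))
}

#' Read a cohort table from delimited text
#'
#' @param path Path to a delimited cohort file with the schema written by
#'   [write_cohort()].
#' @param sep Field separator.
#' @return A data frame.
#' @export
read_cohort <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
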