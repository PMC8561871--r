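# matclass

Maturity-adjusted weight-status classification for adolescent cohorts.

## The problem

National surveillance programmes classify child weight status by comparing
BMI against age- and sex-matched reference norms (percentile cut-offs on an
LMS growth reference). Around puberty this mismatches children who mature
early or late: children enter puberty up to six years apart, and an
early-maturing 11-year-old carries the stature and fat mass of a
developmentally older child, so her BMI looks high against same-aged peers
even when it is unremarkable for her maturational stage. `matclass` is for
biostatisticians and growth researchers who want to re-evaluate weight
status against **biological** rather than chronological age, and to ask
whether doing so improves the prediction of later weight status and
cardiometabolic risk.

## What it computes

**Biological age.** Adult stature is predicted from current stature `H`,
weight `W` and mid-parent stature `MP` with age- and sex-specific linear
coefficients (the Khamis-Roche approach):

    H_adult = a(t) + b1(t) H + b2(t) W + b3(t) MP

The percent of adult height attained, `100 H / H_adult`, is located on a
sex-specific reference curve of mean percent-of-adult-height by age (built
as `100 M_height(t) / mean adult stature`, e.g. 177.6 cm for men and
163.7 cm for women); the age at which the average child attains the same
percent is the child's biological age. Children whose biological age is
at least one year ahead of (behind) chronological age are early (late)
maturers.

**Adjusted BMI percentiles.** BMI percentiles come from the LMS transform
`z = ((x/M)^L - 1) / (L S)` against the reference at a *matching age* —
chronological age for the standard classification, biological age for the
adjusted one — with screening cut-offs: <2nd percentile underweight, 2nd to
<85th healthy weight, 85th to <95th overweight, >=95th obese.

**Cardiometabolic risk.** A composite score over fasting biomarkers, with
`MAP = (SBP + 2 DBP)/3`:

    CMR = z(1/HDL) + z(LDL) + z(glucose) + z(MAP)

(z-scores within the analysis sample; a median split gives low/high risk).

**Model comparison.** Multinomial logistic models (via `nnet`) predict
follow-up BMI category and high cardiometabolic risk from the baseline
category score (healthy 0 / overweight 1 / obese 2) plus sex, ethnicity and
maternal SES, under each matching scheme; deviance-dispersion scaling
(`phi = deviance / residual df`) inflates standard errors, and schemes are
compared by AIC/BIC (`|dBIC| < 2` treated as equivalent fit), transition
tables and Pearson chi-square.

**Synthetic cohorts.** Real cohorts of this kind are access-controlled, so
`generate_cohort()` simulates a two-visit cohort (ages ~11.75 and ~17.71)
with latent maturity offsets, parental statures, a skewed adiposity
distribution, maturity-driven BMI inflation, percentile tracking between
visits and a fasting panel — all seeded and carrying latent truths so the
pipeline's estimates can be validated against known values. The packaged
references are *synthetic* (smooth, anchored, demographically plausible
curves built in code); external LMS/coefficient tables can be supplied as
delimited text.

## Worked example

```r
library(matclass)
refs <- synthetic_references()

# the inverse lookup behind the method, on the packaged female reference
# (girls average 91.5% of adult stature at age 12)
biological_age(91.5, refs$pah$female)
#> [1] 12
classify_timing(10.5, 12)
#>   offset timing
#> 1    1.5  early

# a full synthetic analysis in the strong-tracking regime
syn <- generate_cohort(cohort_config(n = 5000, tracking_rho = 0.95),
                       refs, seed = 42)
analysis <- analyse_cohort(syn$cohort, refs)
print(analysis)
#> Maturity-adjusted weight-status analysis: 5000 children (4899 modelled)
#>   timing: 1035 early / 3794 on-time / 171 late
#>   moved down a category by adjustment (of overweight/obese): 19% (boys 11%, girls 25%)
#>   chronological transition chi2 = 4390.0 (df 4)
#>   biological transition chi2 = 4698.3 (df 4)
#>   weight-status models: dBIC (bio - chron) = -149.22 [meaningfully better]
#>   CMR models:           dBIC (bio - chron) = -9.22 [meaningfully better]
#>   early-maturer OR for overweight/obesity: 3.80 (3.28-4.40)
```

A girl flagged overweight at 11 against her calendar-age peers may be
healthy-weight against her maturational peers: here the adjustment moves
about a quarter of overweight/obese girls (and a tenth of boys) down a
category, early maturers have ~3.8-fold odds of classified overweight or
obesity, and the biologically adjusted baseline categories predict the
age-17 category decisively better by BIC; the cardiometabolic comparison
is an order of magnitude closer (and typically equivalent, |dBIC| < 2, at
realistic cohort sizes of ~1500). `summary(analysis)` prints the descriptive and
transition tables and every model fit; `run_pipeline()` writes the same as
a report bundle with a machine-readable `results.json`.

## Vignette

`vignettes/maturity-adjusted-classification.Rmd` documents the model and
its assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the numerical design
choices (interpolation, tie-breaks, degenerate inputs, convergence).
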