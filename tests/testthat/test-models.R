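test_that("Pearson chi-square matches direct O/E summation", {
  # published 3x3 transition counts: statistic ~634.7 on 4 df
  chron <- pearson_chi2(counts_chron)
  expect_equal(chron$statistic, 634.74, tolerance = 0.01)
  expect_equal(chron$df, 4)
  # proportional rows are exactly independent
  prop <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 2, byrow = TRUE)
  expect_equal(pearson_chi2(prop)$statistic, 0, tolerance = 1e-12)
  # hand computation: E = 5 in every cell
  expect_equal(pearson_chi2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  # brute-force oracle + stats::chisq.test cross-check on random tables
  set.seed(13)
  for (i in 1:20) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(rpois(r * c, 8) + 1, r, c)
    brute <- 0
    for (a in seq_len(r)) for (b in seq_len(c))
      brute <- brute + (m[a, b] - sum(m[a, ]) * sum(m[, b]) / sum(m))^2 /
        (sum(m[a, ]) * sum(m[, b]) / sum(m))
    got <- pearson_chi2(m)
    expect_equal(got$statistic, brute, tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter))
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
})

test_that("row percentages reproduce the published table cells", {
  pc <- row_percentages(counts_chron)
  expect_equal(unname(pc["healthy", "healthy"]), 90)
  expect_equal(unname(pc["obese", ]), c(23, 18, 59))
  pb <- row_percentages(counts_bio)
  expect_equal(unname(pb["obese", ]), c(14, 17, 70))
  expect_equal(unname(pb["overweight", "healthy"]), 45)
  # single-cell rows are 100%
  expect_equal(unname(row_percentages(matrix(c(5, 0, 0, 7), 2))[1, ]),
               c(100, 0))
  # zero rows are NA
  z <- row_percentages(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(all(is.na(z[1, ])))
})

test_that("transition tables build from factors and validate counts", {
  f <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  t <- factor(c("a", "b", "b", "b"), levels = c("a", "b"))
  tab <- transition_table(f, t)
  expect_equal(unclass(tab)[1, ], c(a = 1, b = 1))
  expect_error(transition_table(counts = matrix(1, 1, 2)), "2x2")
  expect_error(transition_table(counts = matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
})

test_that("multinomial fit recovers the closed-form 2x2 odds ratio", {
  d <- data.frame(
    x = rep(c(0, 0, 1, 1), c(40, 10, 20, 30)),
    y = factor(rep(c("a", "b", "a", "b"), c(40, 10, 20, 30)),
               levels = c("a", "b")))
  fit <- fit_multinomial(y ~ x, d)
  expect_equal(unname(fit$coefficients[1, "x"]), log(6), tolerance = 1e-6)
  expect_equal(odds_ratios(fit)$or[2], 6, tolerance = 1e-5)
  expect_equal(fit$levels, c("a", "b"))
})

test_that("two-level multinomial equals an independent binary logit", {
  set.seed(17)
  n <- 400
  x <- rnorm(n); g <- factor(sample(c("m", "f"), n, TRUE))
  y <- factor(ifelse(runif(n) < plogis(-0.4 + 0.9 * x + 0.5 * (g == "m")),
                     "high", "low"), levels = c("low", "high"))
  d <- data.frame(x, g, y)
  fit <- fit_multinomial(y ~ x + g, d)
  ref <- glm(y ~ x + g, d, family = binomial())
  expect_equal(unname(fit$coefficients[1, ]), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$log_lik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # information-criterion identities from (k, n, logLik)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$log_lik, tolerance = 1e-9)
  expect_equal(fit$bic, fit$k * log(fit$n) - 2 * fit$log_lik,
               tolerance = 1e-9)
  expect_equal(fit$bic, BIC(ref), tolerance = 1e-6)
})

test_that("outcome independent of predictors gives null coefficients", {
  set.seed(19)
  d <- data.frame(x = rnorm(2000),
                  y = factor(sample(c("a", "b", "c"), 2000, TRUE)))
  fit <- fit_multinomial(y ~ x, d)
  expect_lt(max(abs(fit$coefficients[, "x"])), 0.12)
})

test_that("known ordinal log-odds are recovered from simulated data", {
  set.seed(23)
  n <- 5000
  score <- sample(0:2, n, TRUE, prob = c(0.7, 0.2, 0.1))
  y <- factor(ifelse(runif(n) < plogis(-1 + 1.2 * score), "high", "low"),
              levels = c("low", "high"))
  fit <- fit_multinomial(y ~ score, data.frame(score, y))
  expect_equal(unname(fit$coefficients[1, "score"]), 1.2, tolerance = 0.1)
  # the modal-prediction classification rate is at least the majority rate
  expect_gte(fit$percent_correct, 100 * max(prop.table(table(y))) - 1e-9)
})

test_that("dispersion scaling inflates errors only", {
  stub <- structure(list(label = "stub", outcome = "y",
                         coefficients = matrix(c(0.5, -1), 1,
                                               dimnames = list("b", c("(Intercept)", "x"))),
                         se = matrix(c(0.2, 0.1), 1,
                                     dimnames = list("b", c("(Intercept)", "x"))),
                         dispersion = 1, scaled = FALSE,
                         deviance = 400, df_residual = 100,
                         log_lik = -200, k = 2, n = 102,
                         aic = 404, bic = 2 * log(102) + 400),
                    class = "cm_fit")
  scaled <- apply_dispersion_scaling(stub)
  expect_equal(scaled$dispersion, 4)
  expect_equal(scaled$se, stub$se * 2)
  expect_equal(scaled$coefficients, stub$coefficients)
  expect_equal(scaled$aic, stub$aic)
  expect_equal(scaled$bic, stub$bic)
  # phi = 1 leaves errors untouched
  stub$deviance <- 100
  expect_equal(apply_dispersion_scaling(stub)$se, stub$se)
  # scaling is idempotent
  expect_equal(apply_dispersion_scaling(scaled)$se, scaled$se)
  # a real fit records phi = deviance / residual df and phi > 0
  set.seed(29)
  d <- data.frame(x = rnorm(300),
                  y = factor(sample(c("a", "b"), 300, TRUE)))
  f <- apply_dispersion_scaling(fit_multinomial(y ~ x, d))
  expect_equal(f$dispersion, f$deviance / f$df_residual)
  expect_gt(f$dispersion, 0)
})

test_that("model comparison applies the two-point BIC rule", {
  set.seed(31)
  d <- data.frame(x = rnorm(500), z = rnorm(500))
  d$y <- factor(ifelse(runif(500) < plogis(0.8 * d$x), "a", "b"))
  f1 <- fit_multinomial(y ~ x, d, label = "signal")
  f2 <- fit_multinomial(y ~ z, d, label = "noise")
  same <- compare_models(f1, f1)
  expect_equal(same$delta_bic, 0)
  expect_equal(same$verdict, "equivalent")
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$delta_bic, f2$bic - f1$bic)
  expect_equal(cmp$verdict, "meaningfully better")
  expect_equal(cmp$better, "signal")
  # |dBIC| below 2 is equivalence
  f3 <- f1; f3$bic <- f1$bic + 1.5; f3$label <- "nearby"
  expect_equal(compare_models(f1, f3)$verdict, "equivalent")
  f4 <- f1; f4$n <- f1$n - 1
  expect_error(compare_models(f1, f4), "different numbers")
  f5 <- f1; f5$outcome <- "other"
  expect_error(compare_models(f1, f5), "outcome")
})

test_that("timing odds ratios use the 2x2 closed form with Woolf intervals", {
  timing <- rep(c("early", "early", "on_time", "on_time"),
                c(40, 10, 20, 30))
  outcome <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 20, 30))
  o <- maturity_odds(timing, outcome)
  expect_equal(o$or, 6)
  se <- sqrt(1 / 40 + 1 / 10 + 1 / 20 + 1 / 30)
  expect_equal(o$lower, exp(log(6) - qnorm(0.975) * se))
  # identical rows: OR 1
  t2 <- rep(c("early", "on_time"), each = 20)
  o2 <- maturity_odds(t2, rep(c(TRUE, FALSE), 20))
  expect_equal(o2$or, 1)
  # zero cell triggers the continuity correction
  expect_warning(
    o3 <- maturity_odds(rep(c("early", "on_time"), each = 5),
                        c(rep(TRUE, 5), rep(FALSE, 5))),
    "continuity")
  expect_equal(o3$or, (5.5 * 5.5) / (0.5 * 0.5))
})
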