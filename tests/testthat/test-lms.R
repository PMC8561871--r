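test_that("LMS z-score handles the power and log branches", {
  # value at the median is z = 0 regardless of L and S
  for (L in c(-2, -0.5, 0, 1, 2))
    expect_equal(lms_zscore(20, L, 20, 0.1), 0)
  expect_equal(lms_zscore(22, L = 1, M = 20, S = 0.1), 1)
  # L = 0 forces the log branch: value = M * exp(S) is one SD up
  expect_equal(lms_zscore(20 * exp(0.1), L = 0, M = 20, S = 0.1), 1)
  expect_error(lms_zscore(-1, 1, 20, 0.1), "positive")
  expect_error(lms_zscore(20, 1, -20, 0.1), "positive")
})

test_that("LMS transform round-trips through its inverse", {
  set.seed(42)
  for (L in c(-2, 0, 1, 2)) {
    value <- runif(50, 10, 30)
    z <- lms_zscore(value, L, 20, 0.12)
    back <- lms_inverse(z, L, 20, 0.12)
    expect_equal(back, value, tolerance = 1e-9)
  }
})

test_that("percentile conversion matches numerical integration and inverts", {
  expect_equal(zscore_to_percentile(0), 50)
  # oracle: integrate the normal density directly
  oracle <- 100 * integrate(dnorm, -Inf, 1.6449)$value
  expect_equal(zscore_to_percentile(1.6449), oracle, tolerance = 1e-6)
  expect_equal(zscore_to_percentile(1.6449), 95, tolerance = 0.01)
  z <- seq(-3, 3, by = 0.25)
  expect_equal(percentile_to_zscore(zscore_to_percentile(z)), z,
               tolerance = 1e-6)
  # strictly increasing in the measurement at fixed parameters
  v <- seq(15, 30, by = 0.5)
  p <- zscore_to_percentile(lms_zscore(v, -1.5, 20, 0.12))
  expect_true(all(diff(p) > 0))
  expect_error(zscore_to_percentile(Inf), "finite")
})

test_that("age interpolation is linear, exact at grid ages, bounded", {
  hit <- lms_lookup(tiny_height, 11)
  expect_equal(hit$M, 145)
  expect_equal(hit$L, 1)
  mid <- lms_lookup(tiny_height, 10.5)
  expect_equal(mid$M, 142.5)
  # brute-force bracketing oracle: interpolated M within the bracketing rows
  set.seed(7)
  ages <- runif(100, 10, 13)
  M <- lms_lookup(tiny_height, ages)$M
  for (i in seq_along(ages)) {
    lo <- max(which(tiny_height$age <= ages[i]))
    hi <- min(which(tiny_height$age >= ages[i]))
    expect_gte(M[i], min(tiny_height$M[c(lo, hi)]))
    expect_lte(M[i], max(tiny_height$M[c(lo, hi)]))
  }
  expect_error(lms_lookup(tiny_height, 9.9), "span")
  expect_error(lms_lookup(tiny_height, 13.1), "span")
})

test_that("lms_table enforces its invariants", {
  expect_error(lms_table(c(10, 10), c(1, 1), c(1, 1), c(1, 1)), "increasing")
  expect_error(lms_table(10, 1, 1, 1), "two age rows")
  expect_error(lms_table(c(10, 11), c(1, 1), c(-1, 1), c(1, 1)), "positive")
  expect_error(adult_norms(male = 139), "140")
})

test_that("percent-adult-height reference divides medians by the adult norm", {
  # girls' median at 12 is anchored at 91.5% of 163.7 cm
  expect_equal(pah_at_age(tiny_pah, 12), 91.5, tolerance = 1e-9)
  # median equal to the norm is 100%
  t <- lms_table(c(17, 18), c(1, 1), c(163.0, 163.7), c(0.04, 0.04),
                 sex = "female", measurement = "height")
  p <- build_pah_reference(t, adult_norms())
  expect_equal(max(p$percent), 100)
  # monotone medians give a monotone percent curve
  expect_true(all(diff(tiny_pah$percent) >= 0))
  # invariant to uniform rescaling of the M curve and the norm together
  sc <- 1.1
  t2 <- lms_table(c(10, 11, 12), rep(1, 3), sc * c(140, 145, 150),
                  rep(0.04, 3), sex = "male", measurement = "height")
  t1 <- lms_table(c(10, 11, 12), rep(1, 3), c(140, 145, 150),
                  rep(0.04, 3), sex = "male", measurement = "height")
  p1 <- build_pah_reference(t1, adult_norms(male = 177.6))
  p2 <- build_pah_reference(t2, adult_norms(male = 177.6 * sc))
  expect_equal(p1$percent, p2$percent, tolerance = 1e-12)
})

test_that("reference files round-trip through the delimited format", {
  tables <- list(height = list(female = tiny_height),
                 bmi = list(male = refs$bmi$male))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lms_reference(tables, path)
  back <- read_lms_reference(path)
  expect_equal(back$height$female$M, tiny_height$M, tolerance = 1e-9)
  expect_equal(back$bmi$male$L, refs$bmi$male$L, tolerance = 1e-9)
  expect_equal(attr(back$height$female, "sex"), "female")
  # missing column is a named schema error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("measurement,sex,age_years,L,M", bad)
  expect_error(read_lms_reference(bad), "missing column")
})
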