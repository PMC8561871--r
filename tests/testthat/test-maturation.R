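test_that("adult-height prediction is the age-interpolated linear form", {
  # identity coefficients return the current stature
  ident <- kr_table(c(10, 12), intercept = c(0, 0),
                    beta_stature = c(1, 1), beta_weight = c(0, 0),
                    beta_midparent = c(0, 0), sex = "female")
  expect_warning(p <- predict_adult_height(11, 150, 40, 170, ident), NA)
  expect_equal(p, 150)
  # hand linear combination
  one <- kr_table(c(10, 12), intercept = c(10, 10),
                  beta_stature = c(0.5, 0.5), beta_weight = c(0.1, 0.1),
                  beta_midparent = c(0.4, 0.4), sex = "female")
  expect_equal(predict_adult_height(11, 150, 40, 170, one),
               10 + 75 + 4 + 68)
  # interpolation oracle: prediction at the midpoint age equals the mean of
  # the two bracketing rows' predictions (linear in the coefficients)
  two <- kr_table(c(10, 12), intercept = c(5, 15),
                  beta_stature = c(0.4, 0.6), beta_weight = c(0.05, 0.15),
                  beta_midparent = c(0.5, 0.3), sex = "male")
  brute <- mean(c(5 + 0.4 * 150 + 0.05 * 40 + 0.5 * 170,
                  15 + 0.6 * 150 + 0.15 * 40 + 0.3 * 170))
  expect_equal(predict_adult_height(11, 150, 40, 170, two), brute)
  expect_error(predict_adult_height(9, 150, 40, 170, two), "span")
  expect_error(predict_adult_height(11, -150, 40, 170, two), "positive")
  # a prediction below current stature warns but is returned
  low <- kr_table(c(10, 12), intercept = c(0, 0), beta_stature = c(0.5, 0.5),
                  beta_weight = c(0, 0), beta_midparent = c(0, 0),
                  sex = "male")
  expect_warning(predict_adult_height(11, 150, 40, 170, low),
                 "below current stature")
})

test_that("percent of adult height is the capped ratio", {
  expect_equal(percent_adult_height(0.915 * 163.7, 163.7), 91.5)
  expect_equal(percent_adult_height(163.7, 163.7), 100)
  # scale invariance
  expect_equal(percent_adult_height(74.895, 81.85),
               percent_adult_height(149.79, 163.7))
  expect_warning(p <- percent_adult_height(165, 163.7), "capped")
  expect_equal(p, 100)
  expect_error(percent_adult_height(150, 0), "positive")
})

test_that("biological age inverts the reference curve", {
  # the worked anchor: 91.5% maps to exactly age 12 on the girls' curve
  expect_equal(biological_age(91.5, tiny_pah), 12)
  # a percent equal to the curve's value at the child's own age returns it
  own <- pah_at_age(tiny_pah, 11.3)
  expect_equal(biological_age(own, tiny_pah), 11.3, tolerance = 1e-9)
  # dense grid-scan oracle: forward lookup of the returned age reproduces
  # the queried percent
  set.seed(3)
  pcts <- runif(200, min(tiny_pah$percent) + 0.01,
                max(tiny_pah$percent) - 0.01)
  ages <- biological_age(pcts, tiny_pah)
  expect_equal(pah_at_age(tiny_pah, ages), pcts, tolerance = 1e-9)
  # non-decreasing in percent
  expect_true(all(diff(ages[order(pcts)]) >= 0))
  # out-of-range errors report the clamping boundary
  expect_error(biological_age(50, tiny_pah), "age 10")
  expect_error(biological_age(99.9, tiny_pah), "age 14")
  # flat segments resolve to their youngest age
  flat <- structure(data.frame(age = c(16, 17, 18, 19),
                               percent = c(99, 100, 100, 100)),
                    sex = "female", class = c("pah_reference", "data.frame"))
  expect_equal(biological_age(100, flat), 17)
})

test_that("timing classification applies the one-year rule inclusively", {
  w <- classify_timing(10.5, 12.0)
  expect_equal(w$offset, 1.5)
  expect_equal(as.character(w$timing), "early")
  expect_equal(as.character(classify_timing(11, 11)$timing), "on_time")
  expect_equal(as.character(classify_timing(11, 12)$timing), "early")
  expect_equal(as.character(classify_timing(12, 11)$timing), "late")
  expect_equal(as.character(classify_timing(11, 11.999)$timing), "on_time")
  # antisymmetry: swapping the two ages maps early <-> late
  set.seed(5)
  a <- runif(50, 9, 13); b <- runif(50, 9, 13)
  fwd <- classify_timing(a, b)$timing
  rev <- classify_timing(b, a)$timing
  expect_equal(fwd == "early", rev == "late")
  expect_equal(fwd == "on_time", rev == "on_time")
})

test_that("assess_maturity chains the steps consistently", {
  kr <- refs$kr$female
  out <- assess_maturity(age = c(10.5, 11.8), stature = c(149.79, 144),
                         weight = c(40, 38), midparent = c(170.65, 170.65),
                         coeffs = kr, reference = refs$pah$female)
  expect_equal(out$percent_adult_height,
               100 * c(149.79, 144) / out$predicted_adult_height)
  expect_equal(out$offset, out$biological_age - c(10.5, 11.8))
  expect_s3_class(out$timing, "factor")
})
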