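# shared fixtures, built in code

refs <- synthetic_references()

# tiny hand-made LMS table for interpolation tests
tiny_height <- lms_table(age = c(10, 11, 12, 13),
                         L = c(1, 1, 1, 1),
                         M = c(140, 145, 150, 154),
                         S = c(0.04, 0.041, 0.042, 0.042),
                         sex = "female", measurement = "height")

# percent-adult-height reference embedding the 91.5%-at-12 anchor:
# M(12) = 0.915 * 163.7
tiny_pah <- build_pah_reference(
  lms_table(age = c(10, 11, 12, 13, 14),
            L = rep(1, 5),
            M = 163.7 * c(0.852, 0.883, 0.915, 0.950, 0.974),
            S = rep(0.042, 5),
            sex = "female", measurement = "height"),
  adult_norms())

# the printed 3x3 visit-1 -> visit-2 transition counts used throughout
counts_chron <- matrix(c(963, 85, 17, 79, 50, 33, 38, 30, 98),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(c("healthy", "overweight", "obese"),
                                       c("healthy", "overweight", "obese")))
counts_bio <- matrix(c(990, 101, 26, 76, 46, 46, 15, 18, 76),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("healthy", "overweight", "obese"),
                                     c("healthy", "overweight", "obese")))
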