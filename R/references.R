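# Synthetic reference set. National growth references (e.g. the UK 1990
# tables) are licensed datasets that cannot be redistributed, so the package
# constructs a labelled synthetic stand-in with the same structure: per-sex
# LMS tables for height and BMI on a dense age grid, adult stature norms, a
# percent-adult-height curve derived from the height medians, and an
# internally consistent Khamis-Roche-style coefficient table.

# monotone interpolation of anchor points onto a dense grid
.mono_curve <- function(anchor_age, anchor_val, grid) {
  f <- stats::splinefun(anchor_age, anchor_val, method = "hyman")
  f(grid)
}

# Percent-of-adult-height anchors. Two values are pinned deliberately:
# girls average 91.5% of adult stature at age 12, boys 84% at age 11.75.
.PAH_ANCHORS <- list(
  female = list(
    age = c(6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 20),
    pct = c(73, 76.2, 79.2, 82.2, 85.2, 88.3, 91.5, 95, 97.4, 98.8,
            99.5, 99.85, 100, 100)),
  male = list(
    age = c(6, 7, 8, 9, 10, 11, 11.75, 13, 14, 15, 16, 17, 18, 20),
    pct = c(67.5, 70.5, 73.3, 76, 78.7, 81.5, 84, 88.5, 92.5, 96,
            98.2, 99.4, 100, 100)))

.BMI_ANCHORS <- list(
  female = list(
    age = c(6, 8, 10, 11, 12, 13, 14, 15, 16, 17, 18, 20),
    M = c(15.3, 15.8, 16.9, 17.6, 18.4, 19.1, 19.8, 20.3, 20.8, 21.1,
          21.4, 21.8),
    L = -1.6, S = 0.135),
  male = list(
    age = c(6, 8, 10, 11, 12, 13, 14, 15, 16, 17, 18, 20),
    M = c(15.5, 15.9, 16.7, 17.3, 18.0, 18.7, 19.4, 20.1, 20.8, 21.4,
          21.9, 22.5),
    L = -1.9, S = 0.13))

.HEIGHT_S <- c(male = 0.040, female = 0.042)

#' Construct the package's synthetic growth-reference set
#'
#' Builds, entirely in code, the reference inputs the pipeline needs:
#' sex-specific LMS tables for height-for-age and BMI-for-age on a dense age
#' grid (6-20 years, 0.1-year steps), adult stature norms (177.6 cm male,
#' 163.7 cm female by default), percent-of-adult-height curves derived from
#' the height medians, and a Khamis-Roche-style coefficient table.
#'
#' The curves are *synthetic*: smooth, monotone, demographically plausible
#' shapes anchored so that girls average 91.5% of adult stature at age 12 and
#' boys 84% at age 11.75. They are not the UK 1990 values (which are not
#' redistributable) and are intended for simulation and testing, or as a
#' template for the file formats through which real references are supplied
#' ([read_lms_reference()], [read_kr_table()]).
#'
#' The coefficient table is constructed to be internally consistent with the
#' height and BMI references: at every age, a child on the reference median
#' for height and BMI whose parents both have the mean adult stature is
#' predicted to reach exactly the adult norm. Stature weight rises linearly
#' to 1 at age 18 while the weight and mid-parent terms shrink to 0, so at 18
#' the prediction equals attained stature.
#'
#' @param norms An [adult_norms()] object.
#' @param age_step Grid resolution in years (default 0.1).
#' @return A list of class `"growth_refs"` with elements `height`, `bmi`
#'   (each a list with `male` / `female` [lms_table()]s), `norms`, `pah`
#'   (per-sex [build_pah_reference()] curves) and `kr` (per-sex
#'   [kr_table()]s).
#' @export
synthetic_references <- function(norms = adult_norms(), age_step = 0.1) {
  grid <- round(seq(6, 20, by = age_step), 10)
  refs <- list(height = list(), bmi = list(), norms = norms,
               pah = list(), kr = list())
  for (sex in c("male", "female")) {
    an <- .PAH_ANCHORS[[sex]]
    pct <- pmin(.mono_curve(an$age, an$pct, grid), 100)
    M_h <- norms[[sex]] * pct / 100
    refs$height[[sex]] <- lms_table(grid, L = rep(1, length(grid)), M = M_h,
                                    S = rep(.HEIGHT_S[[sex]], length(grid)),
                                    sex = sex, measurement = "height")
    bm <- .BMI_ANCHORS[[sex]]
    M_b <- .mono_curve(bm$age, bm$M, grid)
    refs$bmi[[sex]] <- lms_table(grid, L = rep(bm$L, length(grid)), M = M_b,
                                 S = rep(bm$S, length(grid)),
                                 sex = sex, measurement = "bmi")
    refs$pah[[sex]] <- build_pah_reference(refs$height[[sex]], norms)
    refs$kr[[sex]] <- .synthetic_kr(refs$height[[sex]], refs$bmi[[sex]],
                                    norms, sex)
  }
  structure(refs, class = "growth_refs")
}

# coefficient table consistent with the references: median child of average
# parents predicts the adult norm at every age
.synthetic_kr <- function(height_table, bmi_table, norms, sex) {
  ages <- seq(8, 18, by = 0.5)
  mid_mean <- (norms$male + norms$female) / 2
  M_h <- stats::approx(height_table$age, height_table$M, xout = ages)$y
  M_b <- stats::approx(bmi_table$age, bmi_table$M, xout = ages)$y
  w_med <- M_b * (M_h / 100)^2
  b_s <- 0.45 + 0.55 * (ages - 8) / 10
  b_w <- 0.07 * (18 - ages) / 10
  b_mp <- 0.40 * (18 - ages) / 10
  a0 <- norms[[sex]] - b_s * M_h - b_w * w_med - b_mp * mid_mean
  kr_table(ages, a0, b_s, b_w, b_mp, sex = sex)
}

#' @export
print.growth_refs <- function(x, ...) {
  cat("Synthetic growth-reference set\n")
  cat(sprintf("  adult norms: male %.1f cm, female %.1f cm\n",
              x$norms$male, x$norms$female))
  cat(sprintf("  height/BMI LMS grids: ages %.1f-%.1f y (%d rows per table)\n",
              min(x$height$male$age), max(x$height$male$age),
              nrow(x$height$male)))
  cat(sprintf("  coefficient tables: ages %.1f-%.1f y\n",
              min(x$kr$male$age), max(x$kr$male$age)))
  invisible(x)
}

# internal accessor with sex checking
.ref_for <- function(refs, what, sex) {
  stopifnot(inherits(refs, "growth_refs"))
  t <- refs[[what]][[sex]]
  if (is.null(t)) stop(sprintf("no %s reference for sex '%s'", what, sex))
  t
}
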