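#' Specify the generating model for one analyte
#'
#' The synthetic cohort draws each healthy result from a Box-Cox-normal
#' component: on the transformed scale the value is Gaussian with an
#' age-dependent location `mu(age)` (piecewise-linear between knots) and a
#' constant scale `sigma`. A pathological subpopulation is mixed in as a
#' single shifted, widened Gaussian on the same transformed scale,
#' emulating the deficiency/excess patients that routine laboratory data
#' contain and that the indirect estimator must resist.
#'
#' @param analyte Analyte code, one of `"Cu"`, `"Zn"`, `"Ca"`, `"Mg"`,
#'   `"Fe"`, `"Pb"`.
#' @param unit Free-text unit label (opaque; carried through to output).
#' @param lambda Named numeric `c(M = , F = )`: Box-Cox power per sex (a
#'   scalar is recycled to both sexes).
#' @param mu_knots Named list `list(M = , F = )` of two-column matrices
#'   `cbind(age_months, mu)`; ages strictly increasing within \[0, 216\].
#'   `mu` is the healthy location on the transformed scale.
#' @param sigma Named numeric `c(M = , F = )`, healthy transformed-scale
#'   SD (> 0); scalar recycled.
#' @param contamination_fraction Proportion of pathological results, in
#'   \[0, 0.5).
#' @param contamination_shift Pathological location offset, in units of
#'   the healthy `sigma`, on the transformed scale (default +3).
#' @param contamination_sigma_factor Pathological SD as a multiple of the
#'   healthy `sigma` (default 1.5).
#' @return An object of class `"pedri_analyte_model"`.
#' @export
analyte_model <- function(analyte, unit, lambda, mu_knots, sigma,
                          contamination_fraction = 0,
                          contamination_shift = 3,
                          contamination_sigma_factor = 1.5) {
  stopifnot(analyte %in% c("Cu", "Zn", "Ca", "Mg", "Fe", "Pb"))
  if (length(lambda) == 1L) lambda <- c(M = unname(lambda), F = unname(lambda))
  if (length(sigma) == 1L) sigma <- c(M = unname(sigma), F = unname(sigma))
  stopifnot(all(c("M", "F") %in% names(lambda)),
            all(c("M", "F") %in% names(sigma)),
            all(c("M", "F") %in% names(mu_knots)),
            all(sigma > 0),
            contamination_fraction >= 0, contamination_fraction < 0.5,
            contamination_sigma_factor > 0)
  for (s in c("M", "F")) {
    kn <- mu_knots[[s]]
    stopifnot(is.matrix(kn), ncol(kn) == 2L, nrow(kn) >= 1L,
              all(diff(kn[, 1]) > 0) || nrow(kn) == 1L,
              all(kn[, 1] >= 0), all(kn[, 1] <= 216))
  }
  structure(list(analyte = analyte, unit = unit, lambda = lambda,
                 mu_knots = mu_knots, sigma = sigma,
                 contamination_fraction = contamination_fraction,
                 contamination_shift = contamination_shift,
                 contamination_sigma_factor = contamination_sigma_factor),
            class = "pedri_analyte_model")
}

#' Assemble a full cohort configuration
#'
#' @param analyte_models List of [analyte_model()] objects, named by
#'   analyte code.
#' @param age_weights Named numeric vector: sampling probability per
#'   whole-year age bin (names `"0"`, `"1"`, ... are the bin's lower year;
#'   bin `y` covers months `[12y, 12y + 12)`). Must be non-negative and
#'   sum to 1 within `1e-9`.
#' @param sex_ratio Proportion of males, in (0, 1).
#' @param n_subjects Records to draw per analyte (positive integer).
#' @return An object of class `"pedri_cohort_config"`.
#' @export
cohort_config <- function(analyte_models, age_weights, sex_ratio,
                          n_subjects) {
  stopifnot(length(analyte_models) >= 1L,
            all(vapply(analyte_models, inherits, TRUE,
                       "pedri_analyte_model")),
            !is.null(names(age_weights)), all(age_weights >= 0),
            abs(sum(age_weights) - 1) < 1e-9,
            sex_ratio > 0, sex_ratio < 1,
            n_subjects >= 1)
  names(analyte_models) <- vapply(analyte_models, `[[`, "", "analyte")
  structure(list(analyte_models = analyte_models,
                 age_weights = age_weights,
                 sex_ratio = sex_ratio,
                 n_subjects = as.integer(n_subjects)),
            class = "pedri_cohort_config")
}

# piecewise-linear interpolation of the transformed-scale location,
# constant extrapolation beyond the outermost knots
mu_at_age <- function(model, sex, age_months) {
  kn <- model$mu_knots[[sex]]
  if (nrow(kn) == 1L) return(rep(kn[1, 2], length(age_months)))
  stats::approx(kn[, 1], kn[, 2], xout = age_months, rule = 2)$y
}

# knots given as original-scale medians, stored on the transformed scale
knots_bc <- function(ages, medians, lambda) {
  cbind(ages, box_cox(medians, lambda))
}

#' Default synthetic trace-element cohort
#'
#' Emulates a mixed-outpatient pediatric cohort (ages 0 to <16 years) for
#' whole-blood Cu, Zn, Ca, Mg, Fe and Pb. The age-frequency profile peaks
#' at 1 to <2 years (17.75%) and is sparse beyond 14 years; 56.32% of
#' records are male. Healthy medians at the cohort median age (48 months)
#' sit near 19.74 (Cu, umol/L), 74.80 (Zn, umol/L), 1.60 (Ca, mmol/L),
#' 1.52 (Mg, mmol/L), 7.84 (Fe, mmol/L) and 126.09 (Pb); Cu, Ca and Pb
#' decline with age, Zn and Fe rise, Mg is flat, and Pb turns upward
#' after 15 years. By default 19.2% of records are pathological (shifted
#' +3 healthy SDs on the transformed scale, 1.5x wider), the excluded-
#' abnormal fraction typical of unscreened outpatient data.
#'
#' @param n_subjects Records per analyte (default 3933).
#' @param contamination_fraction Pathological mixing proportion applied
#'   to every analyte (default 0.192).
#' @return A `"pedri_cohort_config"`.
#' @export
default_config <- function(n_subjects = 3933,
                           contamination_fraction = 0.192) {
  w <- c(`0` = 4.81, `1` = 17.75, `2` = 10.93, `3` = 10.17, `4` = 9.71,
         `5` = 7.07, `6` = 6.84, `7` = 6.74, `8` = 5.75, `9` = 5.87,
         `10` = 4.78, `11` = 3.71, `12` = 3.36, `13` = 1.93,
         `14` = 0.41, `15` = 0.18)
  w <- w / sum(w)
  mk <- function(analyte, unit, lambda, ages, med_m, med_f, sigma) {
    analyte_model(
      analyte, unit, lambda,
      mu_knots = list(M = knots_bc(ages, med_m, lambda),
                      F = knots_bc(ages, med_f, lambda)),
      sigma = sigma,
      contamination_fraction = contamination_fraction)
  }
  models <- list(
    mk("Cu", "umol/L", 1, c(0, 48, 216),
       med_m = c(21.8, 19.90, 16.6), med_f = c(21.6, 19.60, 16.4),
       sigma = 4.5),
    mk("Zn", "umol/L", 1, c(0, 48, 216),
       med_m = c(52, 75.5, 96), med_f = c(51, 74.0, 94),
       sigma = 9),
    mk("Ca", "mmol/L", 1, c(0, 48, 216),
       med_m = c(1.71, 1.61, 1.49), med_f = c(1.69, 1.59, 1.47),
       sigma = 0.07),
    mk("Mg", "mmol/L", 1, c(0, 216),
       med_m = c(1.53, 1.53), med_f = c(1.51, 1.51),
       sigma = 0.12),
    mk("Fe", "mmol/L", 1, c(0, 48, 216),
       med_m = c(6.60, 7.90, 8.95), med_f = c(6.50, 7.76, 8.80),
       sigma = 0.55),
    mk("Pb", "mmol/L", 0, c(0, 48, 156, 216),
       med_m = c(170, 128, 70, 110), med_f = c(160, 124, 66, 104),
       sigma = 0.85))
  cohort_config(models, age_weights = w, sex_ratio = 0.5632,
                n_subjects = n_subjects)
}

#' Simulate a measurement table from a cohort configuration
#'
#' Each record independently samples a whole-year age bin from
#' `age_weights` (uniform integer month within the bin), a sex from
#' `sex_ratio`, and a health status from the analyte's
#' `contamination_fraction`; the value is drawn from the corresponding
#' Gaussian component on the transformed scale and back-transformed.
#' Draws whose back-transform would be non-positive (possible only for
#' `lambda > 0` far tails) are redrawn; the count is recorded in the
#' `"n_resampled"` attribute. Output is bit-identical for identical
#' `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return Data frame with columns `subject_id`, `age_months`, `sex`,
#'   `analyte`, `value`, `unit`, `truth_flag` (`"healthy"` or
#'   `"pathological"`), `n_subjects` rows per analyte.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "pedri_cohort_config"))
  set.seed(as.integer(seed))
  n <- config$n_subjects
  years <- as.integer(names(config$age_weights))
  out <- vector("list", length(config$analyte_models))
  n_resampled <- 0L
  for (k in seq_along(config$analyte_models)) {
    m <- config$analyte_models[[k]]
    yr <- years[sample.int(length(years), n, replace = TRUE,
                           prob = config$age_weights)]
    age <- 12L * yr + sample.int(12L, n, replace = TRUE) - 1L
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "M", "F")
    path <- stats::runif(n) < m$contamination_fraction
    value <- numeric(n)
    for (s in c("M", "F")) {
      i <- which(sex == s)
      if (!length(i)) next
      mu <- mu_at_age(m, s, age[i])
      sd_i <- m$sigma[[s]] *
        ifelse(path[i], m$contamination_sigma_factor, 1)
      mu_i <- mu + ifelse(path[i], m$contamination_shift * m$sigma[[s]], 0)
      y <- stats::rnorm(length(i), mu_i, sd_i)
      lam <- m$lambda[[s]]
      if (abs(lam) >= 1e-8) {
        bad <- which(lam * y + 1 <= 0)
        tries <- 0L
        while (length(bad) && tries < 100L) {
          n_resampled <- n_resampled + length(bad)
          y[bad] <- stats::rnorm(length(bad), mu_i[bad], sd_i[bad])
          bad <- bad[lam * y[bad] + 1 <= 0]
          tries <- tries + 1L
        }
        if (length(bad)) stop("generate_cohort: cannot draw positive values;",
                              " check the configuration")
      }
      value[i] <- inverse_box_cox(y, lam)
    }
    out[[k]] <- data.frame(
      subject_id = sprintf("%s%06d", m$analyte, seq_len(n)),
      age_months = age, sex = sex, analyte = m$analyte,
      value = value, unit = m$unit,
      truth_flag = ifelse(path, "pathological", "healthy"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_resampled") <- n_resampled
  res
}

#' Closed-form generating reference limits
#'
#' The true 2.5th, 50th and 97.5th percentiles of the healthy component
#' at a given age: the inverse Box-Cox of `mu(age) + z_p * sigma`.
#' Contamination is ignored by construction, which is exactly what makes
#' these limits the recovery oracle for the indirect estimator.
#'
#' @param config A [cohort_config()].
#' @param analyte Analyte code present in the config.
#' @param sex `"M"` or `"F"`.
#' @param age_months Age in months (within the knot range).
#' @return Named numeric `c(lower = , median = , upper = )`.
#' @export
true_reference_limits <- function(config, analyte, sex, age_months) {
  stopifnot(inherits(config, "pedri_cohort_config"),
            analyte %in% names(config$analyte_models),
            sex %in% c("M", "F"))
  m <- config$analyte_models[[analyte]]
  mu <- mu_at_age(m, sex, age_months)
  z <- stats::qnorm(c(0.025, 0.5, 0.975))
  lim <- inverse_box_cox(mu + z * m$sigma[[sex]], m$lambda[[sex]])
  c(lower = lim[1], median = lim[2], upper = lim[3])
}
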