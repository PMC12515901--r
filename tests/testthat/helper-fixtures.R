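# Single flat-trend Box-Cox component wrapped in a one-analyte cohort
# config: the workhorse fixture for estimator tests (age plays no role).
flat_component_config <- function(analyte = "Cu", unit = "umol/L",
                                  lambda = 1, med = 19.9, sigma = 4.5,
                                  frac = 0, shift = 3, sigma_factor = 1.5,
                                  n = 2000) {
  m <- analyte_model(
    analyte, unit, lambda,
    mu_knots = list(M = cbind(0, box_cox(med, lambda)),
                    F = cbind(0, box_cox(med, lambda))),
    sigma = sigma,
    contamination_fraction = frac,
    contamination_shift = shift,
    contamination_sigma_factor = sigma_factor)
  cohort_config(list(m), age_weights = c(`4` = 1), sex_ratio = 0.5,
                n_subjects = n)
}

# Two-regime cohort: mean jump at `cut` months, unit SD, ages uniform.
step_cohort <- function(n = 1000, seed = 1, cut = 60, mu1 = 10, mu2 = 13,
                        sd = 1, age_max = 119) {
  set.seed(seed)
  age <- sample(0:age_max, n, replace = TRUE)
  data.frame(age_months = age,
             value = stats::rnorm(n, ifelse(age < cut, mu1, mu2), sd))
}

# Independent quantile oracle: R's own mode-7 implementation.
quantile_oracle <- function(values, p) {
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

# Exhaustive first-cut oracle: scan every midpoint between consecutive
# distinct ages, computing SSEs naively with mean(); youngest tie wins.
first_cut_oracle <- function(ages, values, min_leaf) {
  a <- sort(unique(ages))
  if (length(a) < 2L) return(NULL)
  mids <- (a[-1] + a[-length(a)]) / 2
  sse <- function(x) sum((x - mean(x))^2)
  best_cut <- NULL
  best_gain <- -Inf
  total <- sse(values)
  for (m in mids) {
    l <- values[ages < m]; r <- values[ages >= m]
    if (length(l) < min_leaf || length(r) < min_leaf) next
    gain <- total - (sse(l) + sse(r))
    if (gain > best_gain + 1e-12 * max(total, 1)) {
      best_gain <- gain
      best_cut <- m
    }
  }
  if (!is.null(best_cut) && best_gain <= 1e-12 * max(total, 1)) return(NULL)
  best_cut
}
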