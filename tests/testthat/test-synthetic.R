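test_that("default cohort configuration encodes the study's structure", {
  cfg <- default_config()
  expect_equal(sum(cfg$age_weights), 1, tolerance = 1e-12)
  # mode of the age profile: 1 to <2 years at ~17.75%
  expect_equal(unname(cfg$age_weights["1"]), 0.1775, tolerance = 5e-3)
  expect_equal(unname(which.max(cfg$age_weights)), 2L)  # the "1" bin
  expect_equal(cfg$sex_ratio, 0.5632)
  # Mg: flat age trend (all knot locations equal, both sexes)
  for (s in c("M", "F")) {
    kn <- cfg$analyte_models$Mg$mu_knots[[s]]
    expect_equal(diff(range(kn[, 2])), 0)
  }
  expect_setequal(names(cfg$analyte_models),
                  c("Cu", "Zn", "Ca", "Mg", "Fe", "Pb"))
})

test_that("simulated healthy medians sit near the configured targets", {
  cfg <- default_config(contamination_fraction = 0)
  cu_only <- cohort_config(list(cfg$analyte_models$Cu),
                           age_weights = cfg$age_weights,
                           sex_ratio = cfg$sex_ratio, n_subjects = 50000)
  co <- generate_cohort(cu_only, seed = 1)
  expect_lt(abs(median(co$value) - 19.74) / 19.74, 0.10)
})

test_that("generation is deterministic and honours the mixture", {
  cfg <- flat_component_config(frac = 0, n = 500)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$truth_flag == "healthy"))

  cfg2 <- flat_component_config(frac = 0.192, n = 5000)
  co <- generate_cohort(cfg2, seed = 2)
  phat <- mean(co$truth_flag == "pathological")
  expect_lt(abs(phat - 0.192), 3 * sqrt(0.192 * 0.808 / 5000))
})

test_that("empirical healthy quantiles converge to the closed-form limits", {
  cfg <- flat_component_config(frac = 0, n = 100000)
  co <- generate_cohort(cfg, seed = 4)
  tr <- true_reference_limits(cfg, "Cu", "M", 48)
  emp <- compute_quantile(co$value, c(0.025, 0.975))
  expect_lt(abs(emp[1] - tr["lower"]) / tr["lower"], 0.01)
  expect_lt(abs(emp[2] - tr["upper"]) / tr["upper"], 0.01)
})

test_that("default age trends run in the documented directions", {
  cfg <- default_config()
  med <- function(an, age) true_reference_limits(cfg, an, "M", age)["median"]
  expect_gt(med("Cu", 12), med("Cu", 120))  # falls with age
  expect_gt(med("Ca", 12), med("Ca", 120))
  expect_gt(med("Pb", 12), med("Pb", 120))
  expect_lt(med("Zn", 12), med("Zn", 120))  # rises with age
  expect_lt(med("Fe", 12), med("Fe", 120))
  expect_equal(unname(med("Mg", 12)), unname(med("Mg", 120)))
})

test_that("closed-form limits match the normal and lognormal cases", {
  z <- qnorm(0.975)
  cfg <- flat_component_config(lambda = 1, med = 100, sigma = 10)
  tr <- true_reference_limits(cfg, "Cu", "M", 48)
  expect_equal(unname(tr), c(100 - z * 10, 100, 100 + z * 10))
  expect_equal(unname(tr), c(80.4, 100, 119.6), tolerance = 1e-4)

  cfg0 <- flat_component_config(lambda = 0, med = 100, sigma = 0.1)
  tr0 <- true_reference_limits(cfg0, "Cu", "M", 48)
  expect_equal(unname(tr0), c(100 * exp(-z * 0.1), 100, 100 * exp(z * 0.1)))
  # ordering holds for any component
  set.seed(31)
  for (i in 1:20) {
    cfg_i <- flat_component_config(lambda = runif(1, 0, 2),
                                   med = runif(1, 5, 200),
                                   sigma = runif(1, 0.05, 0.3))
    tr_i <- true_reference_limits(cfg_i, "Cu", "M", 48)
    expect_true(tr_i[1] < tr_i[2] && tr_i[2] < tr_i[3])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(analyte_model("Cu", "u", 1,
    mu_knots = list(M = cbind(c(10, 5), c(1, 2)),
                    F = cbind(0, 1)), sigma = 1))  # non-increasing knots
  expect_error(analyte_model("Cu", "u", 1,
    mu_knots = list(M = cbind(0, 1), F = cbind(0, 1)),
    sigma = 1, contamination_fraction = 0.6))      # fraction >= 0.5
  m <- analyte_model("Cu", "u", 1,
    mu_knots = list(M = cbind(0, 1), F = cbind(0, 1)), sigma = 1)
  expect_error(cohort_config(list(m), age_weights = c(`1` = 0.7),
                             sex_ratio = 0.5, n_subjects = 10))  # sum != 1
})
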