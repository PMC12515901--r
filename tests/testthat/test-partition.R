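test_that("subgroup summaries reproduce hand-computed statistics", {
  one <- data.frame(age_months = 5, value = 7.3)
  s <- subgroup_summaries(one, c(0, 12))
  expect_equal(s$mean, 7.3)
  expect_equal(s$sd, 0)
  expect_equal(c(s$q025, s$q500, s$q975), rep(7.3, 3))

  rec <- data.frame(age_months = rep(3, 8), value = c(2, 4, 4, 4, 5, 5, 7, 9))
  s <- subgroup_summaries(rec, c(0, 12))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, sqrt(32 / 7))          # 2.138, n-1 denominator
  expect_equal(s$n, 8L)

  set.seed(8)
  rec2 <- data.frame(age_months = sample(0:35, 60, TRUE), value = rnorm(60))
  perm <- rec2[sample(nrow(rec2)), ]
  expect_equal(subgroup_summaries(rec2, c(0, 12, 24, 36)),
               subgroup_summaries(perm, c(0, 12, 24, 36)))
  expect_warning(subgroup_summaries(one, c(0, 3, 12)), "empty bin")
})

test_that("Harris-Boyd statistic and critical value follow the formulas", {
  s1 <- list(n = 50, mean = 4, sd = 1.2)
  hb0 <- harris_boyd(s1, s1)
  expect_equal(hb0$z, 0)
  expect_equal(hb0$sd_ratio, 1)
  expect_false(hb0$split_by_z || hb0$split_by_sd)

  # the size-scaled critical value is exactly 3 at n1 + n2 = 240
  hb <- harris_boyd(list(n = 120, mean = 1, sd = 1),
                    list(n = 120, mean = 1, sd = 1))
  expect_identical(hb$z_star, 3)

  hb2 <- harris_boyd(list(n = 100, mean = 10, sd = 2),
                     list(n = 100, mean = 12, sd = 2))
  expect_equal(hb2$z, -7.0711, tolerance = 1e-4)
  expect_equal(hb2$z_star, 2.7386, tolerance = 1e-4)
  expect_true(hb2$split_by_z)
  expect_false(hb2$split_by_sd)
})

test_that("Harris-Boyd is antisymmetric and z* grows with pooled n", {
  set.seed(14)
  for (i in 1:50) {
    a <- list(n = sample(2:500, 1), mean = rnorm(1), sd = runif(1, 0.1, 3))
    b <- list(n = sample(2:500, 1), mean = rnorm(1), sd = runif(1, 0.1, 3))
    f <- harris_boyd(a, b); g <- harris_boyd(b, a)
    expect_equal(f$z, -g$z)
    expect_identical(f$z_star, g$z_star)
    expect_identical(c(f$split_by_z, f$split_by_sd),
                     c(g$split_by_z, g$split_by_sd))
  }
  zs <- sapply(c(60, 120, 240, 480), function(n)
    harris_boyd(list(n = n, mean = 0, sd = 1),
                list(n = n, mean = 0, sd = 1))$z_star)
  expect_true(all(diff(zs) > 0))
})

test_that("Lahti proportions: identical subgroups share the common limits", {
  set.seed(17)
  v <- runif(1000)
  l <- lahti(v, v)
  expect_false(l$split)
  expect_equal(unname(l$proportions[c(1, 2)]),
               unname(l$proportions[c(3, 4)]))
  expect_true(all(l$proportions > 0.9 & l$proportions < 4.1))
})

test_that("Lahti proportions match brute-force counting exactly", {
  set.seed(23)
  for (i in 1:20) {
    v1 <- rnorm(sample(120:400, 1))
    v2 <- rnorm(sample(120:400, 1), mean = runif(1, 0, 2))
    l <- lahti(v1, v2)
    lim <- quantile_oracle(c(v1, v2), c(0.025, 0.975))
    count_below <- function(v, L) { k <- 0; for (x in v) if (x < L) k <- k + 1; k }
    count_above <- function(v, U) { k <- 0; for (x in v) if (x > U) k <- k + 1; k }
    expect_equal(unname(l$proportions),
                 100 * c(count_below(v1, lim[1]) / length(v1),
                         count_above(v1, lim[2]) / length(v1),
                         count_below(v2, lim[1]) / length(v2),
                         count_above(v2, lim[2]) / length(v2)),
                 tolerance = 1e-12)
  }
})

test_that("Lahti verdicts are affine-equivariant and need adequate n", {
  set.seed(29)
  v1 <- rnorm(300); v2 <- rnorm(300, 0.5)
  l <- lahti(v1, v2)
  l2 <- lahti(3 + 2.5 * v1, 3 + 2.5 * v2)
  expect_equal(l$proportions, l2$proportions)
  expect_identical(l$split, l2$split)
  expect_error(lahti(rnorm(100), rnorm(300)),
               class = "pedri_lahti_insufficient")

  # a three-SD shift pushes one subgroup's tail out of the common limits
  set.seed(11)
  a <- rnorm(500); b <- rnorm(500, 3)
  l3 <- lahti(a, b)
  expect_true(l3$split)
  expect_gte(unname(l3$proportions["p2_above"]), 4.1)
})

test_that("age tree finds the dominant cut and respects its contract", {
  expect_length(fit_age_tree(rep(1:10, 10), rep(2, 100), min_leaf = 10), 0)
  expect_length(fit_age_tree(1:30, rnorm(30), min_leaf = 20), 0)  # n < 2*min_leaf

  set.seed(3)
  age <- sample(0:119, 1000, replace = TRUE)
  val <- rnorm(1000, ifelse(age < 60, 10, 20), 1)
  first <- fit_age_tree(age, val, max_depth = 1, min_leaf = 50)
  expect_length(first, 1)
  expect_gte(first, 54); expect_lte(first, 66)
  cuts <- fit_age_tree(age, val, max_depth = 2, min_leaf = 50)
  expect_lte(length(cuts), 3)
  expect_true(any(cuts >= 54 & cuts <= 66))
})

test_that("tree first cut equals the exhaustive-scan oracle at small n", {
  set.seed(37)
  for (i in 1:20) {
    n <- sample(40:200, 1)
    age <- sample(0:36, n, replace = TRUE)
    val <- rnorm(n) + ifelse(age < sample(6:30, 1), 0, runif(1, 0, 3))
    mine <- fit_age_tree(age, val, max_depth = 1, min_leaf = 10)
    oracle <- first_cut_oracle(age, val, min_leaf = 10)
    if (is.null(oracle)) expect_length(mine, 0) else expect_equal(mine, oracle)
  }
})

test_that("tree first cut agrees with rpart on step data", {
  set.seed(41)
  age <- sample(0:119, 800, replace = TRUE)
  val <- rnorm(800, ifelse(age < 60, 0, 3), 1)
  mine <- fit_age_tree(age, val, max_depth = 1, min_leaf = 50)
  fit <- rpart::rpart(val ~ age, data = data.frame(age, val),
                      control = rpart::rpart.control(
                        maxdepth = 1, minbucket = 50, minsplit = 100,
                        cp = 0, xval = 0))
  expect_equal(mine, fit$splits[1, "index"], tolerance = 1)
})

test_that("refined partitions are disjoint, contiguous and well-sized", {
  for (s in c(2, 13)) {
    rec <- step_cohort(seed = s)
    p <- refine_partition(rec, fit_age_tree(rec$age_months, rec$value, 2, 50),
                          min_leaf = 50)
    expect_equal(p$bins$age_lo[-1], p$bins$age_hi[-nrow(p$bins)])
    expect_equal(p$bins$age_lo[1], min(rec$age_months))
    expect_equal(p$bins$age_hi[nrow(p$bins)], max(rec$age_months) + 1)
    expect_true(all(p$bins$n >= 50))
    expect_equal(sum(p$bins$n), nrow(rec))
    expect_lte(p$passes, 20)
    expect_s3_class(p, "pedri_partition")
  }
})

test_that("refinement detects a three-SD changepoint without proliferating", {
  found <- 0
  for (s in 1:10) {
    rec <- step_cohort(seed = s)
    p <- refine_partition(rec, fit_age_tree(rec$age_months, rec$value, 2, 50),
                          min_leaf = 50)
    interior <- p$edges[-c(1, length(p$edges))]
    if (any(interior >= 54 & interior <= 66)) found <- found + 1
    expect_lte(length(interior), 5)
  }
  expect_equal(found, 10)
})

test_that("homogeneous cohorts usually collapse to a single bin", {
  ones <- 0
  for (s in 1:8) {
    set.seed(s + 1000)
    age <- sample(0:191, 2000, replace = TRUE)
    rec <- data.frame(age_months = age, value = rnorm(2000, 10, 1))
    p <- refine_partition(rec, fit_age_tree(age, rec$value, 2, 50),
                          min_leaf = 50)
    if (nrow(p$bins) == 1) ones <- ones + 1
  }
  expect_gte(ones, 4)
})
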