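test_that("ancova group F reduces to one-way ANOVA without covariates", {
  d <- tibble::tibble(value = c(1, 2, 3, 3, 4, 5),
                      group = rep(c("a", "b"), each = 3))
  res <- ancova_group_effect(d, covariates = character(0))
  expect_equal(res$F, 6, tolerance = 1e-12)
  expect_equal(c(res$df1, res$df2), c(1, 4))
  expect_equal(res$p, 1 - pf(6, 1, 4), tolerance = 1e-12)
})

test_that("ancova degrees of freedom follow the covariate count", {
  d <- simulated_metric_tbl(20, 0, 0.5, seed = 3)
  res <- ancova_group_effect(d)
  expect_equal(c(res$df1, res$df2), c(1, 35))
  res_edu <- ancova_group_effect(d, covariates = c("age", "sex",
                                                   "handedness", "education"))
  expect_equal(res_edu$df2, 34)

  d$group2 <- as.numeric(d$group == "a")
  expect_error(
    ancova_group_effect(d, covariates = c("age", "group2")),
    class = "leidar_collinearity"
  )
})

test_that("BH adjustment matches the hand-computed step-up", {
  p_in <- c(0.004, 0.378, 0.842, 0.774, 0.021)
  # by hand: sort, multiply by m/rank, enforce monotonicity from the bottom
  expect_equal(fdr_adjust(p_in), c(0.020, 0.630, 0.842, 0.842, 0.0525),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(rep(0.3, 4)), rep(0.3, 4))
  expect_equal(fdr_adjust(0.123), 0.123)
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "leidar_invalid_config")
})

test_that("BH adjustment is monotone, idempotent, and never decreases p", {
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(15)
    a <- fdr_adjust(p)
    expect_true(all(a >= p))
    expect_true(all(a <= 1))
    # monotone along the sorted input
    expect_true(all(diff(a[order(p)]) >= -1e-12))
  }
})

test_that("BIC Bayes factor follows the stated arithmetic", {
  d <- simulated_metric_tbl(20, 0, 1.5, sd1 = 1, sd2 = 1, seed = 4)
  bf <- bayes_factor_group(d)
  expect_equal(bf$bf10, exp((bf$bic_null - bf$bic_full) / 2),
               tolerance = 1e-12)
  expect_gt(bf$bf10, 0)
  # when the group explains nothing, the extra parameter is penalized
  set.seed(1)
  same <- bayes_factor_group(
    d |> dplyr::mutate(value = age + rnorm(40, 0, 0.1)),
    covariates = "age"
  )
  expect_lt(same$bf10, 1)
})

test_that("a strong planted effect earns BF10 > 3 in at least 90% of seeds", {
  hits <- vapply(1:50, function(s) {
    d <- simulated_metric_tbl(20, 0.136, 0.209, sd1 = 0.045, sd2 = 0.053,
                              seed = s)
    bayes_factor_group(d)$bf10 > 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("partial spearman recovers perfect monotone association", {
  d <- simulated_metric_tbl(20, seed = 5)
  d$x <- rnorm(40)
  d$y <- d$x
  res <- partial_spearman(d, "x", "y")
  expect_equal(res$rho, 1, tolerance = 1e-9)
  expect_lt(res$p, 1e-10)
  d$y <- -d$x
  expect_equal(partial_spearman(d, "x", "y")$rho, -1, tolerance = 1e-9)
  expect_equal(res$df, 40 - 2 - 4)
})

test_that("partial spearman is calibrated under the null", {
  set.seed(9)
  rejections <- vapply(1:1000, function(i) {
    d <- tibble::tibble(
      x = rnorm(40), y = rnorm(40), age = rnorm(40),
      group = rep(0:1, 20)
    )
    partial_spearman(d, "x", "y", covariates = c("age", "group"))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("stats battery produces the full table structure", {
  coh <- tiny_cohort(n_per_group = 8, seed = 21)
  lab_tbl <- coh$subjects |>
    dplyr::transmute(subject_id, group, labels = truth_labels)
  metrics <- cohort_metrics(lab_tbl, 3, tr = 2)
  covars <- coh$subjects[, c("subject_id", "group", "age", "sex",
                             "handedness", "education")]
  res <- run_stats_battery(metrics, covars)
  expect_s3_class(res, "leida_stats")
  expect_equal(nrow(res$states), 6)        # occupancy + lifetime x 3 states
  expect_equal(nrow(res$transitions), 6)   # 3 x 2 directed pairs
  expect_true(all(res$states$p_fdr >= res$states$p - 1e-12))
  expect_true(all(res$transitions$exploratory))

  res_edu <- run_stats_battery(metrics, covars,
                               covariates = c("age", "sex", "handedness",
                                              "education"))
  expect_equal(unique(res_edu$states$df2), unique(res$states$df2) - 1)

  td <- tidy(res)
  expect_equal(nrow(td), 12)
  expect_equal(glance(res)$n_state_tests, 6)
})

test_that("exploratory outcome correlations run per metric cell", {
  coh <- tiny_cohort(n_per_group = 10, seed = 31)
  lab_tbl <- coh$subjects |>
    dplyr::transmute(subject_id, group, labels = truth_labels)
  metrics <- cohort_metrics(lab_tbl, 3, tr = 2) |>
    dplyr::filter(metric == "occupancy")
  covars <- coh$subjects[, c("subject_id", "group", "age", "sex",
                             "handedness")]
  set.seed(2)
  outcomes <- tibble::tibble(subject_id = covars$subject_id,
                             fatigue = rnorm(20), il6 = rnorm(20))
  res <- correlate_outcomes(metrics, outcomes, c("fatigue", "il6"), covars)
  expect_equal(nrow(res), 3 * 2)
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(all(res$df == 20 - 2 - 4))
})
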