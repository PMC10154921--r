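metrics_fixture <- function() {
  tibble::tibble(
    site = rep(c("A", "B", "C"), each = 3),
    treatment = rep(c("control", "medium", "high"), 3),
    n_nodes = c(10L, 10L, 5L, 8L, 9L, 3L, 12L, 11L, 7L),
    n_connections = c(20L, 22L, 10L, 12L, 12L, 5L, 25L, 20L, 15L),
    n_reg_rece = c(5L, 5L, 2L, 3L, 4L, 1L, 6L, 5L, 3L),
    n_reg_rese = c(4L, 3L, 1L, 2L, 2L, 1L, 5L, 4L, 2L),
    mean_eigencentrality = c(0.6, 0.5, 0.2, 0.3, 0.35, 0.1, 0.7, 0.6, 0.3)
  )
}

test_that("effect sizes are treatment/control ratios joined to baseline complexity", {
  eff <- effect_sizes(metrics_fixture())
  expect_equal(nrow(eff), 3 * 2 * 4) # sites x levels x metrics
  a_high_nodes <- eff[eff$site == "A" & eff$level == "high" &
                        eff$metric == "n_nodes", ]
  expect_equal(a_high_nodes$effect, 0.5)
  expect_equal(a_high_nodes$baseline_complexity, 0.6)
  a_med_nodes <- eff[eff$site == "A" & eff$level == "medium" &
                       eff$metric == "n_nodes", ]
  expect_equal(a_med_nodes$effect, 1)

  # scale invariance: doubling one site's control and treatment values
  # leaves its ratios unchanged
  m2 <- metrics_fixture()
  cols <- c("n_nodes", "n_connections", "n_reg_rece", "n_reg_rese")
  m2[m2$site == "A", cols] <- m2[m2$site == "A", cols] * 2L
  expect_equal(effect_sizes(m2)$effect, eff$effect)

  # a missing control names the site
  expect_error(effect_sizes(metrics_fixture()[-1, ]), "A")
})

test_that("zero-control metrics are emitted undefined and excluded downstream", {
  m <- metrics_fixture()
  m$n_reg_rese[m$site == "B" & m$treatment == "control"] <- 0L
  expect_warning(eff <- effect_sizes(m), "undefined")
  na_rows <- eff[is.na(eff$effect), ]
  expect_equal(nrow(na_rows), 2) # both levels at site B
  expect_true(all(na_rows$metric == "n_reg_rese"))
  tests <- effect_size_tests(eff)
  expect_true(all(tests$n[tests$metric == "n_reg_rese"] <
                    tests$n[tests$metric == "n_nodes"]))
})

test_that("one-sample t matches direct formula arithmetic", {
  r <- one_sample_t(c(0.8, 1.0, 1.2), mu = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- one_sample_t(c(0.5, 0.6, 0.7), mu = 1)
  expect_equal(r$statistic, (0.6 - 1) / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$statistic, -6.9282, tolerance = 1e-4)
  expect_equal(r$p_value, 2 * stats::pt(r$statistic, df = 2), tolerance = 1e-10)
  expect_equal(r$p_value, 0.0202, tolerance = 1e-3)
  expect_error(one_sample_t(c(1, 1, 1)), "variance")
  expect_error(one_sample_t(1), "at least 2")
})

test_that("t statistics match a direct high-precision reference on random fixtures", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n, mean = 1, sd = 0.4)
    mu <- stats::runif(1, 0.5, 1.5)
    r <- one_sample_t(x, mu = mu)
    t_ref <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
    expect_equal(r$statistic, t_ref, tolerance = 1e-10)
    expect_equal(r$p_value, 2 * stats::pt(-abs(t_ref), df = n - 1),
                 tolerance = 1e-10)

    m <- sample(3:12, 1)
    y <- stats::rnorm(m, mean = 0.8, sd = 0.6)
    r2 <- two_sample_t(x, y)
    se <- sqrt(stats::var(x) / n + stats::var(y) / m)
    t2_ref <- (mean(x) - mean(y)) / se
    df_ref <- se^4 / ((stats::var(x) / n)^2 / (n - 1) +
                        (stats::var(y) / m)^2 / (m - 1))
    expect_equal(r2$statistic, t2_ref, tolerance = 1e-10)
    expect_equal(r2$df, df_ref, tolerance = 1e-10)
    expect_equal(r2$p_value, 2 * stats::pt(-abs(t2_ref), df = df_ref),
                 tolerance = 1e-10)
  }
})

test_that("two-sample t direction and fixtures behave", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  shifted <- two_sample_t(c(2, 3, 4), c(1, 2, 3))
  expect_gt(shifted$statistic, 0)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "constant")
})

test_that("effect-size tests cover every metric and comparison", {
  eff <- effect_sizes(metrics_fixture())
  tests <- effect_size_tests(eff)
  expect_setequal(unique(tests$comparison),
                  c("medium vs 1", "high vs 1", "medium vs high"))
  expect_setequal(unique(tests$metric),
                  c("n_nodes", "n_connections", "n_reg_rece", "n_reg_rese"))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  expect_s3_class(tidy(tests), "tbl_df")
  # BH adjustment never lowers a p-value
  tests_bh <- effect_size_tests(eff, p_adjust = "BH")
  expect_true(all(tests_bh$p_value >= tests$p_value - 1e-12))
})
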