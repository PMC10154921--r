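#' Nutrient treatment effect sizes
#'
#' For each site, enrichment level and network metric, the effect size is
#' the treatment value divided by the site's control value — values below 1
#' indicate metric loss under enrichment. Each record carries the site's
#' baseline network complexity (control mean node eigencentrality). Sites
#' whose control value for a metric is 0 have an undefined ratio; these are
#' emitted with `effect = NA` and a warning, and are dropped by downstream
#' tests and fits.
#'
#' @param metrics Metrics table from [network_metrics()]: one row per
#'   site-treatment with the five metric columns. Every site must have a
#'   `control` row.
#' @param metric_names Metrics to form ratios for; defaults to the four
#'   count metrics (nodes, connections, REG~REC_e, REG~RES_e).
#' @return A tibble `(site, level, metric, effect, baseline_complexity)`,
#'   one row per site x non-control level x metric.
#' @export
effect_sizes <- function(metrics, metric_names = COUNT_METRICS) {
  metrics <- as_tibble(metrics)
  missing_cols <- setdiff(c("site", "treatment", metric_names, "mean_eigencentrality"),
                          names(metrics))
  if (length(missing_cols) > 0) {
    abort(paste0("Metrics table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ctrl <- metrics %>% filter(.data$treatment == "control")
  no_ctrl <- setdiff(unique(metrics$site), ctrl$site)
  if (length(no_ctrl) > 0) {
    abort(paste0("Site(s) without a control row: ", paste(no_ctrl, collapse = ", ")))
  }
  long <- metrics %>%
    select("site", "treatment", dplyr::all_of(metric_names)) %>%
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value")
  ctrl_long <- long %>%
    filter(.data$treatment == "control") %>%
    select("site", "metric", control_value = "value")
  baseline <- ctrl %>% select("site", baseline_complexity = "mean_eigencentrality")
  out <- long %>%
    filter(.data$treatment != "control") %>%
    rename(level = "treatment") %>%
    left_join(ctrl_long, by = c("site", "metric")) %>%
    left_join(baseline, by = "site") %>%
    mutate(effect = if_else(.data$control_value > 0,
                            .data$value / .data$control_value, NA_real_)) %>%
    select("site", "level", "metric", "effect", "baseline_complexity") %>%
    arrange(.data$site, .data$level, .data$metric)
  n_undef <- sum(is.na(out$effect))
  if (n_undef > 0) {
    warn(sprintf(
      "%d effect size(s) undefined (control metric 0); emitted as NA and excluded downstream.",
      n_undef
    ))
  }
  out
}

#' One- and two-sample t-tests of enrichment effects
#'
#' Per metric and enrichment level, a two-sided one-sample t-test of the
#' effect sizes against 1 (no change from control), plus a two-sample test
#' (Welch by default) comparing medium against high per metric. Undefined
#' (`NA`) effects are dropped.
#'
#' @param effects Effect-size table from [effect_sizes()].
#' @param mu Null value for the one-sample tests; default 1.
#' @param var_equal Use the pooled-variance two-sample test instead of
#'   Welch's. Default `FALSE`.
#' @param p_adjust Optional p-value adjustment method for [stats::p.adjust()]
#'   (e.g. `"BH"`); default `"none"`, mirroring raw per-test reporting.
#' @return A `nat_tests` tibble: `metric`, `comparison` (`medium vs 1`,
#'   `high vs 1`, `medium vs high`), `estimate` (mean effect, or mean
#'   difference for two-sample), `statistic`, `df`, `p_value`, `n`.
#' @export
effect_size_tests <- function(effects, mu = 1, var_equal = FALSE,
                              p_adjust = "none") {
  effects <- as_tibble(effects) %>% filter(!is.na(.data$effect))
  one <- effects %>%
    group_by(.data$metric, .data$level) %>%
    summarise(res = list(one_sample_t(.data$effect, mu = mu)),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(
      comparison = paste(.data$level, "vs", mu),
      estimate = purrr::map_dbl(.data$res, "estimate"),
      statistic = purrr::map_dbl(.data$res, "statistic"),
      df = purrr::map_dbl(.data$res, "df"),
      p_value = purrr::map_dbl(.data$res, "p_value")
    ) %>%
    select("metric", "comparison", "estimate", "statistic", "df", "p_value", "n")
  two <- effects %>%
    group_by(.data$metric) %>%
    summarise(
      res = list(two_sample_t(.data$effect[.data$level == "medium"],
                              .data$effect[.data$level == "high"],
                              var_equal = var_equal)),
      n = dplyr::n(), .groups = "drop"
    ) %>%
    mutate(
      comparison = "medium vs high",
      estimate = purrr::map_dbl(.data$res, "estimate"),
      statistic = purrr::map_dbl(.data$res, "statistic"),
      df = purrr::map_dbl(.data$res, "df"),
      p_value = purrr::map_dbl(.data$res, "p_value")
    ) %>%
    select("metric", "comparison", "estimate", "statistic", "df", "p_value", "n")
  out <- bind_rows(one, two) %>% arrange(.data$metric, .data$comparison)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  class(out) <- c("nat_tests", class(out))
  out
}

#' One-sample t-test
#'
#' Two-sided Student t-test of a sample mean against `mu`.
#'
#' @param values Numeric sample, length >= 2, nonzero variance.
#' @param mu Null mean; default 1 (the no-effect value for ratios).
#' @return List with `estimate` (sample mean), `statistic`, `df`, `p_value`.
#' @export
one_sample_t <- function(values, mu = 1) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("Need at least 2 values for a one-sample t-test.")
  if (sd(values) == 0) abort("Zero sample variance; t statistic undefined.")
  ht <- t.test(values, mu = mu)
  list(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value)
}

#' Two-sample t-test
#'
#' Two-sided two-sample t-test, Welch (unequal variances) by default.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pooled-variance test instead of Welch. Default `FALSE`.
#' @return List with `estimate` (mean(a) - mean(b)), `statistic`, `df`,
#'   `p_value`.
#' @export
two_sample_t <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Need at least 2 values per sample for a two-sample t-test.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    abort("Both samples are constant; t statistic undefined.")
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(estimate = unname(ht$estimate[1] - ht$estimate[2]),
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
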