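#' Run the full network-analysis-of-traits pipeline
#'
#' Orchestrates every stage: pool plots into site-treatment communities,
#' score and filter trait pairs with the exact co-occurrence model, build
#' one trait network per site-treatment, compute pooled node
#' eigencentrality and the per-network metrics, form treatment effect
#' sizes, run the t-tests, and fit the quantile-regression ladder of effect
#' size against baseline network complexity (per metric, with pooled
#' levels), with its convergence summary.
#'
#' @param traits A [trait_matrix()]; binarized with `binarize_threshold` if
#'   not already binary.
#' @param community Long-form community records (see
#'   [validate_community()]).
#' @param e_threshold Expected co-occurrence retention threshold; default 1.
#' @param sig_level Optional `p_gt` significance filter (off by default;
#'   see [filter_trait_pairs()]).
#' @param iterations,weighted,mode Passed to [pooled_eigencentrality()].
#' @param taus Quantile ladder for [quantile_fits()].
#' @param binarize_threshold Threshold for [binarize_traits()] when
#'   `traits` is fuzzy-coded. Default 0.
#' @param out_dir Optional directory; when given, all tables, networks
#'   (GraphML) and a JSON run manifest are written there (see
#'   [write_nat_results()]).
#' @param seed Seed recorded in the manifest and used for export layouts.
#' @return A `nat_results` list: `pair_stats`, `retained`, `networks`,
#'   `scores`, `metrics`, `effects`, `tests`, `quantile_fits` (one
#'   `quantile_fits` object per metric), `convergence` (tibble, one row per
#'   metric), and `config` (the options used).
#' @examples
#' \donttest{
#' dat <- generate_dataset(nat_config(seed = 7, n_sites = 4))
#' res <- run_nat(dat$traits, dat$community)
#' res$metrics
#' }
#' @export
run_nat <- function(traits, community,
                    e_threshold = 1, sig_level = NULL,
                    iterations = 100, weighted = FALSE, mode = "fixed",
                    taus = seq(0.1, 0.9, by = 0.1),
                    binarize_threshold = 0,
                    out_dir = NULL, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  if (!is_binary(traits)) {
    traits <- stage("binarize", binarize_traits(traits, binarize_threshold))
  }
  presence <- stage("pool_plots", pool_plots(community))
  sizes <- community_sizes(presence)
  pair_stats <- stage("score_trait_pairs", score_trait_pairs(presence, traits))
  retained <- stage("filter_trait_pairs",
                    filter_trait_pairs(pair_stats, e_threshold, sig_level))
  networks <- stage("build_networks",
                    build_networks(retained, traits, communities = sizes))
  scores <- stage("pooled_eigencentrality",
                  pooled_eigencentrality(networks, iterations = iterations,
                                         weighted = weighted, mode = mode))
  metrics <- stage("network_metrics", network_metrics(networks, scores))
  effects <- stage("effect_sizes", effect_sizes(metrics))
  tests <- stage("effect_size_tests", effect_size_tests(effects))
  fits <- stage("quantile_fits", {
    ok <- effects %>% filter(!is.na(.data$effect))
    fits <- list()
    for (m in unique(ok$metric)) {
      d <- ok %>% filter(.data$metric == m)
      if (nrow(d) >= 3 && length(unique(d$baseline_complexity)) >= 2) {
        fits[[m]] <- quantile_fits(d, x = "baseline_complexity", y = "effect",
                                   taus = taus)
      }
    }
    fits
  })
  convergence <- purrr::imap(fits, function(f, m) {
    convergence_summary(f, tau_lo = min(taus), tau_hi = max(taus)) %>%
      mutate(metric = m, .before = 1)
  }) %>% bind_rows()
  res <- structure(
    list(
      pair_stats = pair_stats, retained = retained, networks = networks,
      scores = scores, metrics = metrics, effects = effects, tests = tests,
      quantile_fits = fits, convergence = convergence,
      config = list(
        e_threshold = e_threshold, sig_level = sig_level,
        iterations = iterations, weighted = weighted, mode = mode,
        taus = taus, binarize_threshold = binarize_threshold, seed = seed
      )
    ),
    class = "nat_results"
  )
  if (!is.null(out_dir)) write_nat_results(res, out_dir)
  res
}

#' Run the pipeline on a synthetic dataset
#'
#' Convenience wrapper: [generate_dataset()] then [run_nat()].
#'
#' @param config A [nat_config()].
#' @param ... Passed to [run_nat()].
#' @return A `nat_results` object with the dataset attached as `$data`.
#' @export
run_nat_synthetic <- function(config = nat_config(), ...) {
  dat <- generate_dataset(config)
  res <- run_nat(dat$traits, dat$community, seed = config$seed, ...)
  res$data <- dat
  res
}

#' @export
print.nat_results <- function(x, ...) {
  cat(sprintf(
    "<nat_results> %d networks (%d sites), %d retained trait pairs\n",
    nrow(x$networks), length(unique(x$networks$site)), nrow(x$retained)
  ))
  cat("metrics:\n")
  print(x$metrics, n = 6)
  invisible(x)
}

#' Glance at pipeline results
#'
#' @param x A `nat_results` object.
#' @param ... Ignored.
#' @return One-row tibble: network/site counts, mean baseline complexity,
#'   mean medium/high effect size over the count metrics, and the mean
#'   quantile-spread difference across metrics.
#' @export
glance.nat_results <- function(x, ...) {
  eff <- x$effects %>% filter(!is.na(.data$effect))
  tibble(
    n_networks = nrow(x$networks),
    n_sites = length(unique(x$networks$site)),
    n_retained_pairs = nrow(x$retained),
    mean_baseline_complexity = mean(
      x$metrics$mean_eigencentrality[x$metrics$treatment == "control"]
    ),
    mean_effect_medium = mean(eff$effect[eff$level == "medium"]),
    mean_effect_high = mean(eff$effect[eff$level == "high"]),
    mean_spread_difference = if (nrow(x$convergence) > 0) {
      mean(x$convergence$spread_difference)
    } else NA_real_
  )
}

#' Write pipeline results to a directory
#'
#' Writes `metrics.csv`, `effect_sizes.csv`, `pair_stats.csv`,
#' `retained_pairs.csv`, `tests.csv`, `quantile_coefficients.csv`,
#' `convergence.csv`, one GraphML file per non-empty network under
#' `networks/`, and `manifest.json` recording the options, seed and package
#' version.
#'
#' @param res A `nat_results` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_nat_results <- function(res, out_dir) {
  stopifnot(inherits(res, "nat_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }
  wr(res$metrics, "metrics.csv")
  wr(res$effects, "effect_sizes.csv")
  wr(res$pair_stats, "pair_stats.csv")
  wr(res$retained, "retained_pairs.csv")
  wr(tidy(res$tests), "tests.csv")
  if (length(res$quantile_fits) > 0) {
    coefs <- purrr::imap(res$quantile_fits, function(f, m) {
      tidy(f) %>% mutate(metric = m, .before = 1)
    }) %>% bind_rows()
    wr(coefs, "quantile_coefficients.csv")
  }
  if (nrow(res$convergence) > 0) wr(res$convergence, "convergence.csv")
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(res$networks))) {
    net <- res$networks$network[[i]]
    if (nrow(net$edges) == 0) next
    export_network(
      net, file.path(net_dir, sprintf("%s_%s.graphml", net$site, net$treatment)),
      format = "graphml", scores = res$scores,
      layout_seed = res$config$seed
    )
  }
  manifest <- list(
    package = "traitnet",
    version = as.character(utils::packageVersion("traitnet")),
    r_version = as.character(getRversion()),
    config = res$config[!vapply(res$config, is.null, logical(1))],
    n_networks = nrow(res$networks)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
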