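# ggplot2 figures for each result type. All return ggplot objects; nothing
# downstream depends on them.

#' Plot a trait network
#'
#' Force-directed (Fruchterman–Reingold) node-link diagram, nodes coloured
#' by trait category and sized by pooled eigencentrality when supplied,
#' edges weighted by the number of species sharing the pair.
#'
#' @param net A `trait_network`.
#' @param scores Optional pooled eigencentrality scores.
#' @param layout_seed Seed for the layout. Default 1.
#' @return A ggplot object.
#' @export
plot_network <- function(net, scores = NULL, layout_seed = 1) {
  stopifnot(inherits(net, "trait_network"))
  if (nrow(net$nodes) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = sprintf("%s / %s (empty network)",
                                           net$site, net$treatment)))
  }
  g <- as_igraph(net, scores)
  coords <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    modality = igraph::V(g)$name, category = igraph::V(g)$category,
    x = coords[, 1], y = coords[, 2],
    eigencentrality = if (!is.null(scores)) igraph::V(g)$eigencentrality else 1
  )
  pos <- setNames(seq_len(nrow(nodes)), nodes$modality)
  edges <- net$edges %>%
    mutate(
      x = nodes$x[pos[.data$modality_i]], y = nodes$y[pos[.data$modality_i]],
      xend = nodes$x[pos[.data$modality_j]], yend = nodes$y[pos[.data$modality_j]]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      colour = "grey60", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$category,
                   size = .data$eigencentrality)
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::labs(title = sprintf("%s / %s", net$site, net$treatment)) +
    ggplot2::theme_void()
}

#' Effect-size box plots by metric and enrichment level
#'
#' Box-and-whisker view of treatment effect sizes (treatment / control) per
#' network metric and enrichment level, with the no-change line at 1.
#'
#' @param effects Effect-size table from [effect_sizes()].
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(effects) {
  effects <- as_tibble(effects) %>% filter(!is.na(.data$effect))
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$level, y = .data$effect,
                               fill = .data$level)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "enrichment level", y = "effect size (treatment / control)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Effect size versus baseline complexity with quantile lines
#'
#' Scatter of effect size against baseline network complexity with the
#' fitted quantile-regression ladder overlaid; converging lines indicate
#' that response variance shrinks as baseline complexity grows.
#'
#' @param effects Effect-size table (one metric, or faceted by metric).
#' @param fits Named list of `quantile_fits` per metric (as in
#'   `nat_results$quantile_fits`), or a single `quantile_fits` object.
#' @return A ggplot object.
#' @export
plot_convergence <- function(effects, fits) {
  effects <- as_tibble(effects) %>% filter(!is.na(.data$effect))
  if (inherits(fits, "quantile_fits")) fits <- list(all = fits)
  lines <- purrr::imap(fits, function(f, m) {
    grid <- seq(f$x_range[1], f$x_range[2], length.out = 50)
    purrr::map2(f$fits, f$taus, function(fit, tau) {
      tibble(metric = m, tau = tau, baseline_complexity = grid,
             effect = predict(fit, grid))
    }) %>% bind_rows()
  }) %>% bind_rows()
  p <- ggplot2::ggplot(effects,
                       ggplot2::aes(x = .data$baseline_complexity,
                                    y = .data$effect)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$level), size = 1.5) +
    ggplot2::geom_line(
      data = lines,
      ggplot2::aes(group = .data$tau), linetype = 2, colour = "grey30",
      linewidth = 0.4
    ) +
    ggplot2::labs(x = "baseline network complexity (control mean eigencentrality)",
                  y = "effect size (treatment / control)") +
    ggplot2::theme_minimal()
  if (length(fits) > 1 || "metric" %in% names(effects)) {
    p <- p + ggplot2::facet_wrap(~metric, scales = "free_y")
  }
  p
}

#' Baseline complexity against site covariates
#'
#' Descriptive biplots of control network complexity against mean PAR
#' (turbidity proxy, expected negative relation) and porewater NH4
#' (log scale, expected positive relation).
#'
#' @param metrics Metrics table from [network_metrics()].
#' @param covariates Per-site covariates (`site`, `mean_par`,
#'   `porewater_nh4`), e.g. from [generate_dataset()].
#' @return A ggplot object.
#' @export
plot_complexity_covariates <- function(metrics, covariates) {
  baseline <- as_tibble(metrics) %>%
    filter(.data$treatment == "control") %>%
    select("site", "mean_eigencentrality") %>%
    inner_join(as_tibble(covariates), by = "site") %>%
    tidyr::pivot_longer(c("mean_par", "porewater_nh4"),
                        names_to = "covariate", values_to = "value")
  ggplot2::ggplot(baseline,
                  ggplot2::aes(x = .data$value,
                               y = .data$mean_eigencentrality)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "baseline network complexity") +
    ggplot2::theme_minimal()
}

#' @rdname plot_effect_sizes
#' @param object A `nat_results` object.
#' @param type One of `"effects"`, `"convergence"`, `"network"`.
#' @param ... Passed on to the underlying `plot_*` function.
#' @export
autoplot.nat_results <- function(object, type = c("effects", "convergence",
                                                  "network"), ...) {
  type <- match.arg(type)
  switch(type,
    effects = plot_effect_sizes(object$effects),
    convergence = plot_convergence(object$effects, object$quantile_fits),
    network = plot_network(object$networks$network[[1]], object$scores, ...)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
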