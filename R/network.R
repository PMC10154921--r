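#' Build a trait network for one site-treatment
#'
#' Nodes are trait modalities incident to at least one retained pair; edges
#' are the retained pairs with weight equal to the observed co-occurrence
#' (the number of community species bearing both modalities). Modalities
#' with no retained edge are excluded: a network simplifies by losing both
#' connections and the nodes they stranded.
#'
#' @param retained Retained pair statistics for a single community
#'   ([filter_trait_pairs()] output filtered to one site-treatment).
#' @param traits A [trait_matrix()] supplying modality categories.
#' @param site,treatment Identifiers; taken from `retained` when present.
#' @return A `trait_network`: list with `site`, `treatment`, `nodes`
#'   (tibble `modality`, `trait`, `category`) and `edges` (tibble
#'   `modality_i`, `modality_j`, `weight`).
#' @export
build_network <- function(retained, traits, site = NULL, treatment = NULL) {
  retained <- as_tibble(retained)
  if (is.null(site) && "site" %in% names(retained) && nrow(retained) > 0) {
    site <- unique(retained$site)
  }
  if (is.null(treatment) && "treatment" %in% names(retained) && nrow(retained) > 0) {
    treatment <- unique(retained$treatment)
  }
  if (length(site) > 1 || length(treatment) > 1) {
    abort("`retained` must come from a single site-treatment community.")
  }
  key <- paste(pmin(retained$modality_i, retained$modality_j),
               pmax(retained$modality_i, retained$modality_j))
  if (anyDuplicated(key)) {
    abort("Duplicate modality pair(s) in `retained`.")
  }
  if (nrow(retained) > 0 && any(retained$modality_i == retained$modality_j)) {
    abort("Self-loops (pair of a modality with itself) are not allowed.")
  }
  mods <- modalities(traits)
  used <- unique(c(retained$modality_i, retained$modality_j))
  unknown <- setdiff(used, mods$modality)
  if (length(unknown) > 0) {
    abort(paste0("Modalities absent from the trait table: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      site = site %||% NA_character_,
      treatment = treatment %||% NA_character_,
      nodes = mods %>% filter(.data$modality %in% used),
      edges = tibble(
        modality_i = retained$modality_i,
        modality_j = retained$modality_j,
        weight = as.integer(retained$q_obs)
      )
    ),
    class = "trait_network"
  )
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf(
    "<trait_network> site %s / %s: %d nodes, %d connections\n",
    x$site, x$treatment, nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Build trait networks for every site-treatment
#'
#' @param retained Retained pair statistics ([filter_trait_pairs()]), any
#'   number of site-treatments.
#' @param traits A [trait_matrix()].
#' @param communities Optional tibble of `(site, treatment)` (e.g.
#'   [community_sizes()]) naming every community a network should be built
#'   for; communities with no retained pair then yield empty networks.
#'   Defaults to the site-treatments present in `retained`.
#' @return A tibble with columns `site`, `treatment`, and a `network`
#'   list-column of `trait_network` objects.
#' @export
build_networks <- function(retained, traits, communities = NULL) {
  retained <- as_tibble(retained)
  if (is.null(communities)) {
    communities <- retained %>% distinct(.data$site, .data$treatment)
  }
  communities <- as_tibble(communities) %>%
    distinct(.data$site, .data$treatment) %>%
    arrange(.data$site, .data$treatment)
  communities %>%
    mutate(network = purrr::map2(.data$site, .data$treatment, function(s, t) {
      build_network(
        retained %>% filter(.data$site == s, .data$treatment == t),
        traits, site = s, treatment = t
      )
    }))
}

#' Count connections between two trait categories
#'
#' The number of network edges with one endpoint in `cat_a` and the other in
#' `cat_b` (unordered). With `cat_a = cat_b` counts within-category edges.
#' REG~REC_e and REG~RES_e counts index response diversity: connections
#' between ecosystem-regulating and recovery/resistance-enhancing traits.
#'
#' @param net A `trait_network`.
#' @param cat_a,cat_b Trait categories (`REG`, `REC_e`, `REC_i`, `RES_e`,
#'   `RES_i`).
#' @return Integer count.
#' @export
count_category_connections <- function(net, cat_a, cat_b) {
  stopifnot(inherits(net, "trait_network"))
  if (!cat_a %in% TRAIT_CATEGORIES || !cat_b %in% TRAIT_CATEGORIES) {
    abort(paste0("Categories must be one of ", paste(TRAIT_CATEGORIES, collapse = ", "), "."))
  }
  if (nrow(net$edges) == 0) return(0L)
  cat_of <- setNames(net$nodes$category, net$nodes$modality)
  ci <- cat_of[net$edges$modality_i]
  cj <- cat_of[net$edges$modality_j]
  sum((ci == cat_a & cj == cat_b) | (ci == cat_b & cj == cat_a))
}

# ---- pooled eigencentrality ------------------------------------------------

# adjacency matrix of the pooled all-networks graph; nodes keyed
# site|treatment|modality so each site-treatment is its own component
pooled_adjacency <- function(networks, weighted = FALSE) {
  nets <- networks$network
  keys <- character(0)
  from <- character(0); to <- character(0); w <- numeric(0)
  for (net in nets) {
    pref <- paste(net$site, net$treatment, sep = "|")
    if (nrow(net$nodes) > 0) {
      keys <- c(keys, paste(pref, net$nodes$modality, sep = "|"))
    }
    if (nrow(net$edges) > 0) {
      from <- c(from, paste(pref, net$edges$modality_i, sep = "|"))
      to <- c(to, paste(pref, net$edges$modality_j, sep = "|"))
      w <- c(w, net$edges$weight)
    }
  }
  a <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  if (length(from) > 0) {
    val <- if (weighted) w else rep(1, length(w))
    a[cbind(from, to)] <- val
    a[cbind(to, from)] <- val
  }
  a
}

# power iteration with per-iteration max-normalisation; shift > 0 iterates
# on (A + shift I), which has the same dominant eigenvector but converges
# on bipartite components too
power_iteration <- function(a, iterations = 100, shift = 0, tol = NULL) {
  stopifnot(nrow(a) == ncol(a))
  n <- nrow(a)
  if (n == 0) return(numeric(0))
  x <- rep(1, n)
  for (i in seq_len(iterations)) {
    x_new <- as.numeric(a %*% x) + shift * x
    m <- max(abs(x_new))
    if (m == 0) { # no edges at all
      x <- x_new
      break
    }
    x_new <- x_new / m
    if (!is.null(tol) && max(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

#' Pooled node eigencentrality across all networks
#'
#' Eigenvector centrality is a relative measure, so to compare nodes across
#' sites and treatments the scores are computed on one disconnected graph
#' whose components are all the site-treatment networks (each network keeps
#' its own copy of each modality node). The default mirrors the fixed-round
#' power method of common network GUIs: `iterations` rounds of
#' `x <- A x` with max-normalisation after each round, then a final rescale
#' so the global maximum is exactly 1. Isolated nodes score 0.
#'
#' A fixed iteration count (rather than iterating to convergence) is
#' deliberate: run forever, the dominant component drives every other
#' component to zero, whereas a fixed count preserves the cross-component
#' contrast that makes the score a relative complexity measure. Two
#' alternatives are provided: `mode = "converged"` iterates a shifted power
#' method to convergence (per component this equals the dominant eigenvector
#' of the component, max-normalised within the global scale), and
#' `mode = "per_component_scaled"` scales each component's converged
#' eigenvector by its dominant eigenvalue relative to the global maximum
#' eigenvalue.
#'
#' @param networks Tibble from [build_networks()] (columns `site`,
#'   `treatment`, `network`). At least one network must be non-empty.
#' @param iterations Number of power-iteration rounds (default 100).
#' @param weighted Use edge weights in the iteration? Default `FALSE`.
#' @param mode `"fixed"` (default), `"converged"`, or
#'   `"per_component_scaled"`; see Details.
#' @return A tibble `(site, treatment, modality, eigencentrality)` covering
#'   every node of every network; scores lie in `[0, 1]` with maximum 1.
#' @export
pooled_eigencentrality <- function(networks, iterations = 100, weighted = FALSE,
                                   mode = c("fixed", "converged", "per_component_scaled")) {
  mode <- match.arg(mode)
  if (all(purrr::map_int(networks$network, ~ nrow(.x$edges)) == 0)) {
    abort("All networks are empty; pooled eigencentrality is undefined.")
  }
  a <- pooled_adjacency(networks, weighted = weighted)
  if (mode == "fixed") {
    x <- power_iteration(a, iterations = iterations)
  } else {
    comps <- graph_components(a)
    x <- numeric(nrow(a))
    lambdas <- numeric(max(comps))
    vecs <- vector("list", max(comps))
    for (k in seq_len(max(comps))) {
      idx <- which(comps == k)
      sub <- a[idx, idx, drop = FALSE]
      if (all(sub == 0)) { # isolated node(s)
        vecs[[k]] <- rep(0, length(idx)); lambdas[k] <- 0
        next
      }
      v <- power_iteration(sub, iterations = 100000, shift = 1, tol = 1e-13)
      vecs[[k]] <- v / max(abs(v))
      lambdas[k] <- max(as.numeric(sub %*% v) / ifelse(v == 0, Inf, v), 0)
    }
    if (mode == "converged") {
      # dominant component(s) carry scale 1; others keep their own max at 1
      for (k in seq_len(max(comps))) x[comps == k] <- vecs[[k]]
    } else {
      lmax <- max(lambdas)
      for (k in seq_len(max(comps))) {
        x[comps == k] <- vecs[[k]] * (lambdas[k] / lmax)
      }
    }
  }
  m <- max(abs(x))
  if (m > 0) x <- x / m
  keys <- rownames(a)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tibble(
    site = purrr::map_chr(parts, 1),
    treatment = purrr::map_chr(parts, 2),
    modality = purrr::map_chr(parts, 3),
    eigencentrality = x
  )
}

# connected components of an adjacency matrix (label vector)
graph_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(a[v, ] != 0 & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Mean node eigencentrality of one network
#'
#' The arithmetic mean of a network's pooled node scores — the network
#' complexity proxy. Computed from the pooled scores so it remains
#' comparable across sites and treatments.
#'
#' @param scores Output of [pooled_eigencentrality()].
#' @param net A `trait_network`.
#' @return A number in `[0, 1]`; an empty network scores 0, with a warning.
#' @export
mean_node_eigencentrality <- function(scores, net) {
  stopifnot(inherits(net, "trait_network"))
  if (nrow(net$nodes) == 0) {
    warn(sprintf("Empty network (site %s / %s); mean eigencentrality set to 0.",
                 net$site, net$treatment))
    return(0)
  }
  sub <- as_tibble(scores) %>%
    filter(.data$site == net$site, .data$treatment == net$treatment,
           .data$modality %in% net$nodes$modality)
  if (nrow(sub) != nrow(net$nodes)) {
    abort("`scores` do not cover all nodes of the network.")
  }
  mean(sub$eigencentrality)
}

#' Network metrics per site-treatment
#'
#' The five architecture metrics per network: node count, connection count,
#' REG~REC_e and REG~RES_e connection counts, and mean node eigencentrality
#' (from the pooled scores).
#'
#' @param networks Tibble from [build_networks()].
#' @param scores Output of [pooled_eigencentrality()]; computed at defaults
#'   when omitted.
#' @return A tibble with columns `site`, `treatment`, `n_nodes`,
#'   `n_connections`, `n_reg_rece`, `n_reg_rese`, `mean_eigencentrality` —
#'   one row per site-treatment.
#' @export
network_metrics <- function(networks, scores = NULL) {
  if (is.null(scores)) scores <- pooled_eigencentrality(networks)
  networks %>%
    mutate(
      n_nodes = purrr::map_int(.data$network, ~ nrow(.x$nodes)),
      n_connections = purrr::map_int(.data$network, ~ nrow(.x$edges)),
      n_reg_rece = purrr::map_int(.data$network,
        ~ as.integer(count_category_connections(.x, "REG", "REC_e"))),
      n_reg_rese = purrr::map_int(.data$network,
        ~ as.integer(count_category_connections(.x, "REG", "RES_e"))),
      mean_eigencentrality = purrr::map_dbl(.data$network, function(net) {
        if (nrow(net$nodes) == 0) return(0)
        mean_node_eigencentrality(scores, net)
      })
    ) %>%
    select(-"network")
}
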