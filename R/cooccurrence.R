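#' Expected co-occurrence of a trait pair
#'
#' Under random placement of modality membership among the `n` species of a
#' community, the expected number of species bearing both modalities of a
#' pair is `n_i * n_j / n`, where `n_i` and `n_j` are the numbers of species
#' bearing each modality. Pairs expected to co-occur in fewer than one
#' species are filtered out of the networks ([filter_trait_pairs()]) because
#' a pair carried by at most one species carries no response diversity.
#'
#' @param n_i,n_j Number of community species bearing each modality.
#' @param n Community species richness (must be >= 1).
#' @return The expected co-occurrence count (vectorised).
#' @examples
#' expected_cooccurrence(3, 3, 5) # 1.8
#' @export
expected_cooccurrence <- function(n_i, n_j, n) {
  check_cooc_args(n_i, n_j, n)
  n_i * n_j / n
}

check_cooc_args <- function(n_i, n_j, n) {
  if (any(n < 1)) abort("Community richness `n` must be >= 1 (no community, no co-occurrence).")
  if (any(n_i < 0) || any(n_j < 0)) abort("Modality counts must be non-negative.")
  if (any(n_i > n) || any(n_j > n)) abort("Modality counts cannot exceed community richness `n`.")
  invisible(TRUE)
}

#' Exact probability of observing q co-occurrences
#'
#' The probability that exactly `q` of `n` species bear both modalities when
#' `n_i` and `n_j` bearers are placed at random:
#' `C(n_i, q) C(n - n_i, n_j - q) / C(n, n_j)`. Computed by log-factorial
#' accumulation so it stays exact in double precision for communities up to
#' ~1000 species; infeasible `q` get probability 0.
#'
#' @inheritParams expected_cooccurrence
#' @param q Observed co-occurrence count(s).
#' @return Probability (vectorised over `q`).
#' @examples
#' cooccurrence_pmf(3, 3, 5, 0:3) # 0, 0.3, 0.6, 0.1
#' @export
cooccurrence_pmf <- function(n_i, n_j, n, q) {
  check_cooc_args(n_i, n_j, n)
  if (any(q != floor(q))) abort("`q` must be integer-valued.")
  feasible <- q >= max(0, n_i + n_j - n) & q <= min(n_i, n_j)
  out <- numeric(length(q))
  qq <- q[feasible]
  out[feasible] <- exp(
    lchoose(n_i, qq) + lchoose(n - n_i, n_j - qq) - lchoose(n, n_j)
  )
  out
}

#' Tail probabilities of the co-occurrence model
#'
#' Lower and upper tail sums of the exact PMF at an observed count:
#' `p_lt = P(Q <= q_obs)` and `p_gt = P(Q >= q_obs)`. The two tails share
#' the mass at `q_obs`, so `p_lt + p_gt >= 1`. A small `p_gt` flags a pair
#' co-occurring more often than chance.
#'
#' @inheritParams expected_cooccurrence
#' @param q_obs Observed number of species bearing both modalities; must lie
#'   in the feasible range `[max(0, n_i + n_j - n), min(n_i, n_j)]`.
#' @return A named list with `p_lt` and `p_gt`.
#' @export
cooccurrence_pvalues <- function(n_i, n_j, n, q_obs) {
  check_cooc_args(n_i, n_j, n)
  lo <- max(0, n_i + n_j - n)
  hi <- min(n_i, n_j)
  if (q_obs < lo || q_obs > hi || q_obs != floor(q_obs)) {
    abort(sprintf(
      "Infeasible observed co-occurrence %s: must be an integer in [%d, %d].",
      format(q_obs), lo, hi
    ))
  }
  support <- lo:hi
  pmf <- cooccurrence_pmf(n_i, n_j, n, support)
  list(
    p_lt = sum(pmf[support <= q_obs]),
    p_gt = sum(pmf[support >= q_obs])
  )
}

#' Score all trait pairs of one or more communities
#'
#' For every unordered pair of modalities both borne by at least one species
#' of a community, computes the pair's co-occurrence statistics: bearer
#' counts `n_i`/`n_j`, the observed number of species bearing both
#' (`q_obs`, the prospective edge weight), the expected co-occurrence `e`,
#' and exact lower/upper tail probabilities.
#'
#' @param presence Presence records with columns `site`, `treatment`,
#'   `taxon` — typically from [pool_plots()]. All taxa must appear in the
#'   trait table.
#' @param traits A binary [trait_matrix()] (see [binarize_traits()]).
#' @return A tibble with one row per (site, treatment, modality pair):
#'   columns `site`, `treatment`, `modality_i`, `modality_j`, `n`, `n_i`,
#'   `n_j`, `q_obs`, `e`, `p_lt`, `p_gt`. Modality pairs are ordered by the
#'   trait table's column order with `modality_i` first.
#' @export
score_trait_pairs <- function(presence, traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (!is_binary(traits)) {
    abort("Trait matrix must be binary; call `binarize_traits()` first.")
  }
  presence <- as_tibble(presence)
  need <- c("site", "treatment", "taxon")
  if (!all(need %in% names(presence))) {
    abort("`presence` must have columns site, treatment, taxon.")
  }
  missing_taxa <- setdiff(unique(presence$taxon), traits$taxon)
  if (length(missing_taxa) > 0) {
    abort(paste0(
      "Taxa absent from the trait table: ",
      paste(missing_taxa, collapse = ", ")
    ))
  }
  scores <- trait_scores(traits)
  presence %>%
    distinct(.data$site, .data$treatment, .data$taxon) %>%
    group_by(.data$site, .data$treatment) %>%
    dplyr::group_modify(~ score_one_community(.x$taxon, scores)) %>%
    ungroup()
}

# pair statistics for a single community's species vector
score_one_community <- function(taxa, scores) {
  sub <- scores[taxa, , drop = FALSE]
  n <- nrow(sub)
  counts <- colSums(sub)
  active <- names(counts)[counts > 0]
  if (length(active) < 2 || n == 0) {
    return(tibble(
      modality_i = character(), modality_j = character(),
      n = integer(), n_i = integer(), n_j = integer(), q_obs = integer(),
      e = numeric(), p_lt = numeric(), p_gt = numeric()
    ))
  }
  # q_obs for all pairs at once: crossproduct of the presence matrix
  cross <- crossprod(sub[, active, drop = FALSE])
  pairs <- which(upper.tri(cross), arr.ind = TRUE)
  mi <- active[pairs[, 1]]
  mj <- active[pairs[, 2]]
  n_i <- counts[mi]
  n_j <- counts[mj]
  q_obs <- cross[pairs]
  pv <- purrr::map2(seq_along(mi), q_obs, function(k, q) {
    cooccurrence_pvalues(n_i[k], n_j[k], n, q)
  })
  tibble(
    modality_i = mi, modality_j = mj,
    n = as.integer(n), n_i = as.integer(n_i), n_j = as.integer(n_j),
    q_obs = as.integer(q_obs),
    e = expected_cooccurrence(n_i, n_j, n),
    p_lt = purrr::map_dbl(pv, "p_lt"),
    p_gt = purrr::map_dbl(pv, "p_gt")
  )
}

#' Filter trait pairs by expected co-occurrence
#'
#' Retains pairs expected to co-occur at least `e_threshold` times
#' (default 1: pairs expected to share fewer than one species are dropped,
#' as they probabilistically carry no response diversity) and observed in at
#' least one species (`q_obs >= 1`; a zero-weight connection is meaningless
#' when edge weight is the number of species sharing the pair).
#'
#' @param pair_stats Output of [score_trait_pairs()].
#' @param e_threshold Minimum expected co-occurrence; default 1.
#' @param sig_level Optional significance level; when given, additionally
#'   requires `p_gt <= sig_level` (pairs co-occurring significantly more
#'   than chance). Off by default: the expectation threshold, not
#'   significance, defines retention.
#' @param exclude_within_trait If `TRUE`, drop pairs whose two modalities
#'   belong to the same parent trait; requires `traits`.
#' @param traits Trait matrix, only needed for `exclude_within_trait`.
#' @return The retained subset of `pair_stats`.
#' @export
filter_trait_pairs <- function(pair_stats, e_threshold = 1, sig_level = NULL,
                               exclude_within_trait = FALSE, traits = NULL) {
  if (e_threshold < 0) abort("`e_threshold` must be >= 0.")
  out <- as_tibble(pair_stats) %>%
    filter(.data$e >= e_threshold, .data$q_obs >= 1)
  if (!is.null(sig_level)) {
    out <- out %>% filter(.data$p_gt <= sig_level)
  }
  if (exclude_within_trait) {
    if (is.null(traits)) abort("`exclude_within_trait` requires `traits`.")
    mods <- modalities(traits)
    tr <- setNames(mods$trait, mods$modality)
    out <- out %>% filter(tr[.data$modality_i] != tr[.data$modality_j])
  }
  out
}
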