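# Independent oracles used by the tests. These deliberately take the naive
# route (exhaustive enumeration, dense eigen-decomposition, grid search) so
# they never share code with the implementation they check.

# Exact co-occurrence distribution by enumerating every placement of the
# second modality's n_j bearers among n species (first modality borne by
# species 1..n_i). Returns P(Q = q) for q = 0..n.
enum_cooc_pmf <- function(n_i, n_j, n) {
  out <- numeric(n + 1)
  if (n_j == 0) {
    out[1] <- 1
    return(out)
  }
  subsets <- combn(n, n_j)
  bearers_i <- seq_len(n_i)
  for (k in seq_len(ncol(subsets))) {
    q <- sum(subsets[, k] %in% bearers_i)
    out[q + 1] <- out[q + 1] + 1
  }
  out / ncol(subsets)
}

# Dominant eigenvector of a symmetric adjacency matrix, max-normalised.
eigen_oracle <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

# Random connected undirected graph on n nodes: random spanning tree plus
# independent extra edges. Returns the adjacency matrix.
random_connected_graph <- function(n, p_extra = 0.3) {
  a <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample(i - 1, 1)
    a[i, j] <- a[j, i] <- 1
  }
  extra <- which(upper.tri(a) & a == 0)
  on <- extra[stats::runif(length(extra)) < p_extra]
  a[on] <- 1
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# Wrap a plain adjacency matrix as a one-network tibble so the pooled
# eigencentrality machinery can run on it.
adjacency_as_networks <- function(a, site = "s1", treatment = "control") {
  n <- nrow(a)
  mods <- paste0("m", seq_len(n))
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  net <- structure(
    list(
      site = site, treatment = treatment,
      nodes = tibble::tibble(modality = mods, trait = mods, category = "REG"),
      edges = tibble::tibble(
        modality_i = mods[idx[, 1]], modality_j = mods[idx[, 2]],
        weight = as.integer(a[idx])
      )
    ),
    class = "trait_network"
  )
  tibble::tibble(site = site, treatment = treatment, network = list(net))
}

# Minimum pinball loss over a dense grid of candidate lines.
grid_pinball_oracle <- function(x, y, tau,
                                a_grid = seq(min(y) - 1, max(y) + 1, length.out = 81),
                                b_grid = NULL) {
  if (is.null(b_grid)) {
    span <- (max(y) - min(y)) / max(diff(range(x)), 1e-9)
    b_grid <- seq(-3 * span - 1, 3 * span + 1, length.out = 161)
  }
  best <- Inf
  for (b in b_grid) {
    r0 <- y - b * x
    for (a in a_grid) {
      r <- r0 - a
      loss <- sum(r * (tau - (r < 0)))
      if (loss < best) best <- loss
    }
  }
  best
}

# Small handmade trait table: 5 taxa x 6 modalities over all five categories.
make_test_traits <- function() {
  scores <- tibble::tribble(
    ~taxon, ~mix, ~graze, ~disperse, ~burrow, ~surface, ~fragile,
    "sp1", 1, 0, 1, 1, 0, 0,
    "sp2", 1, 1, 1, 0, 1, 0,
    "sp3", 0, 1, 1, 1, 0, 1,
    "sp4", 1, 1, 0, 1, 1, 0,
    "sp5", 1, 0, 1, 1, 0, 1
  )
  mods <- tibble::tribble(
    ~modality, ~trait, ~category,
    "mix", "sediment_mixing", "REG",
    "graze", "feeding", "REG",
    "disperse", "mobility", "REC_e",
    "burrow", "position", "RES_e",
    "surface", "position", "RES_i",
    "fragile", "body", "REC_i"
  )
  trait_matrix(scores, mods)
}

# Small two-site community over the test traits (3 plots each).
make_test_community <- function() {
  tibble::tibble(
    site = rep(c("A", "B"), each = 15),
    treatment = "control",
    plot = rep(rep(c("p1", "p2", "p3"), each = 5), 2),
    taxon = rep(c("sp1", "sp2", "sp3", "sp4", "sp5"), 6),
    count = c(
      2, 0, 1, 0, 3, 0, 0, 0, 0, 2, 1, 0, 0, 1, 0,
      0, 2, 1, 1, 0, 1, 0, 0, 2, 0, 0, 1, 1, 0, 0
    )
  )
}
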