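test_that("symmetric components score equally and the maximum is exactly 1", {
  # triangle with equal weights: all nodes equivalent
  tri <- matrix(1, 3, 3) - diag(3)
  scores <- pooled_eigencentrality(adjacency_as_networks(tri))
  expect_equal(scores$eigencentrality, rep(1, 3))

  # complete graphs and cycles are vertex-transitive too
  for (n in c(4, 6)) {
    kn <- matrix(1, n, n) - diag(n)
    s <- pooled_eigencentrality(adjacency_as_networks(kn), mode = "converged")
    expect_equal(s$eigencentrality, rep(1, n), tolerance = 1e-9)
    cyc <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i %% n + 1
      cyc[i, j] <- cyc[j, i] <- 1
    }
    s <- pooled_eigencentrality(adjacency_as_networks(cyc), mode = "converged")
    expect_equal(s$eigencentrality, rep(1, n), tolerance = 1e-9)
  }
})

test_that("a star run to convergence gives leaves 1/sqrt(k)", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  s <- pooled_eigencentrality(adjacency_as_networks(star), mode = "converged")
  expect_equal(s$eigencentrality[s$modality == "m1"], 1, tolerance = 1e-9)
  expect_equal(s$eigencentrality[s$modality != "m1"], rep(1 / sqrt(3), 3),
               tolerance = 1e-6)
})

test_that("fixed-iteration pooling ranks denser components above sparser ones", {
  # triangle component + single-edge component in one pooled graph
  tri <- adjacency_as_networks(matrix(1, 3, 3) - diag(3), site = "s1")
  edge <- adjacency_as_networks(rbind(c(0, 1), c(1, 0)), site = "s2")
  nets <- dplyr::bind_rows(tri, edge)
  s <- pooled_eigencentrality(nets)
  expect_equal(max(s$eigencentrality), 1)
  tri_scores <- s$eigencentrality[s$site == "s1"]
  edge_scores <- s$eigencentrality[s$site == "s2"]
  expect_true(min(tri_scores) > max(edge_scores))

  # adding an isolated copy of a component never reorders the others
  edge2 <- adjacency_as_networks(rbind(c(0, 1), c(1, 0)), site = "s3")
  s3 <- pooled_eigencentrality(dplyr::bind_rows(tri, edge, edge2))
  expect_equal(
    s3$eigencentrality[s3$site %in% c("s1", "s2")],
    s$eigencentrality
  )

  # an all-empty set of networks is an error
  traits <- make_test_traits()
  empty <- build_networks(
    tibble::tibble(site = character(), treatment = character(),
                   modality_i = character(), modality_j = character(),
                   q_obs = integer()),
    traits,
    communities = tibble::tibble(site = "A", treatment = "control")
  )
  expect_error(pooled_eigencentrality(empty), "empty")
})

test_that("weighted iteration uses edge weights", {
  # path a-b-c with a heavy a-b edge pulls the centre toward a
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 10
  a[2, 3] <- a[3, 2] <- 1
  s_unw <- pooled_eigencentrality(adjacency_as_networks(a), mode = "converged")
  expect_equal(s_unw$eigencentrality[s_unw$modality == "m1"],
               s_unw$eigencentrality[s_unw$modality == "m3"],
               tolerance = 1e-9)
  s_w <- pooled_eigencentrality(adjacency_as_networks(a), weighted = TRUE,
                                mode = "converged")
  expect_gt(s_w$eigencentrality[s_w$modality == "m1"],
            s_w$eigencentrality[s_w$modality == "m3"])
  # oracle: weighted scores match the dense eigenvector of the weight matrix
  expect_equal(s_w$eigencentrality, eigen_oracle(a)[c(1, 2, 3)],
               tolerance = 1e-6)
})

test_that("deleting an edge never increases a component's converged score mass", {
  # the adjacency-weighted score mass x'Ax of the converged (unit) vector is
  # the dominant eigenvalue; removing an edge cannot increase it
  set.seed(99)
  score_mass <- function(a) {
    v <- eigen_oracle(a)
    v <- v / sqrt(sum(v^2))
    drop(v %*% a %*% v)
  }
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    a <- random_connected_graph(n, p_extra = 0.6)
    edges <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    k <- sample(nrow(edges), 1)
    a2 <- a
    a2[edges[k, 1], edges[k, 2]] <- a2[edges[k, 2], edges[k, 1]] <- 0
    g2 <- igraph::graph_from_adjacency_matrix(a2, mode = "undirected")
    if (!igraph::is_connected(g2)) next # keep a single Perron component
    expect_lte(score_mass(a2), score_mass(a) + 1e-12)
  }
})

test_that("per-component scaling preserves eigenvalue-based contrast", {
  tri <- adjacency_as_networks(matrix(1, 3, 3) - diag(3), site = "s1")
  edge <- adjacency_as_networks(rbind(c(0, 1), c(1, 0)), site = "s2")
  s <- pooled_eigencentrality(dplyr::bind_rows(tri, edge),
                              mode = "per_component_scaled")
  # triangle eigenvalue 2, edge eigenvalue 1: edge nodes score 1/2
  expect_equal(s$eigencentrality[s$site == "s1"], rep(1, 3), tolerance = 1e-9)
  expect_equal(s$eigencentrality[s$site == "s2"], rep(0.5, 2), tolerance = 1e-9)
})
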