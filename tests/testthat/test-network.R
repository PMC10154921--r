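retained_fixture <- function() {
  tibble::tibble(
    site = "A", treatment = "control",
    modality_i = c("mix", "mix", "graze"),
    modality_j = c("disperse", "burrow", "burrow"),
    n = 4L, n_i = 3L, n_j = 3L, q_obs = c(2L, 5L, 3L),
    e = 2.25, p_lt = 0.9, p_gt = 0.6
  )
}

test_that("network construction keeps retained pairs as weighted edges", {
  traits <- make_test_traits()
  net <- build_network(retained_fixture(), traits)
  expect_s3_class(net, "trait_network")
  expect_equal(nrow(net$nodes), 4) # mix, graze, disperse, burrow
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$edges$weight, c(2L, 5L, 3L))
  expect_equal(net$site, "A")

  # empty retained list builds an empty network
  empty <- build_network(retained_fixture()[0, ], traits,
                         site = "A", treatment = "high")
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  # duplicated pair (either orientation) is rejected
  dup <- dplyr::bind_rows(
    retained_fixture(),
    dplyr::mutate(retained_fixture()[1, ],
                  modality_i = "disperse", modality_j = "mix")
  )
  expect_error(build_network(dup, traits), "Duplicate")
})

test_that("category connection counts split edges by endpoint categories", {
  traits <- make_test_traits()
  net <- build_network(retained_fixture(), traits)
  # mix-disperse is REG~REC_e; mix-burrow and graze-burrow are REG~RES_e
  expect_equal(count_category_connections(net, "REG", "REC_e"), 1)
  expect_equal(count_category_connections(net, "REG", "RES_e"), 2)
  expect_equal(count_category_connections(net, "REG", "REC_i"), 0L)
  expect_error(count_category_connections(net, "REG", "BAD"), "Categories")

  # a REG-REG edge counts only for the within-REG query
  within <- tibble::tibble(
    site = "A", treatment = "control",
    modality_i = "mix", modality_j = "graze",
    n = 4L, n_i = 3L, n_j = 3L, q_obs = 2L, e = 2.25, p_lt = 1, p_gt = 0.5
  )
  net2 <- build_network(within, traits)
  expect_equal(count_category_connections(net2, "REG", "REG"), 1)
  expect_equal(count_category_connections(net2, "REG", "RES_e"), 0L)
})

test_that("network metrics count nodes, connections and category links", {
  traits <- make_test_traits()
  nets <- build_networks(retained_fixture(), traits)
  scores <- pooled_eigencentrality(nets)
  metrics <- network_metrics(nets, scores)
  expect_equal(metrics$n_nodes, 4L)
  expect_equal(metrics$n_connections, 3L)
  expect_equal(metrics$n_reg_rece, 1L)
  expect_equal(metrics$n_reg_rese, 2L)
  expect_true(metrics$n_reg_rece + metrics$n_reg_rese <= metrics$n_connections)
  expect_true(metrics$mean_eigencentrality >= 0 &&
                metrics$mean_eigencentrality <= 1)

  # metrics are invariant under node relabeling (graph isomorphism)
  relabel <- c(mix = "graze", graze = "mix", disperse = "disperse",
               burrow = "burrow")
  ret2 <- retained_fixture()
  ret2$modality_i <- unname(relabel[ret2$modality_i])
  ret2$modality_j <- unname(relabel[ret2$modality_j])
  nets2 <- build_networks(ret2, traits)
  m2 <- network_metrics(nets2, pooled_eigencentrality(nets2))
  expect_equal(m2[, -(1:2)], metrics[, -(1:2)])
})

test_that("empty networks yield zero metrics with a warning for complexity", {
  traits <- make_test_traits()
  communities <- tibble::tibble(site = c("A", "A"),
                                treatment = c("control", "high"))
  nets <- build_networks(retained_fixture(), traits, communities = communities)
  expect_equal(nrow(nets), 2)
  scores <- pooled_eigencentrality(nets)
  metrics <- network_metrics(nets, scores)
  empty_row <- metrics[metrics$treatment == "high", ]
  expect_equal(empty_row$n_nodes, 0L)
  expect_equal(empty_row$n_connections, 0L)
  expect_equal(empty_row$mean_eigencentrality, 0)
  net_empty <- nets$network[[which(nets$treatment == "high")]]
  expect_warning(mean_node_eigencentrality(scores, net_empty), "Empty network")
})

test_that("exports round-trip through GraphML and write valid GEXF", {
  traits <- make_test_traits()
  nets <- build_networks(retained_fixture(), traits)
  net <- nets$network[[1]]
  scores <- pooled_eigencentrality(nets)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml", scores = scores,
                 layout_seed = 5)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::E(g)$weight, c(2, 5, 3))
  expect_setequal(igraph::V(g)$category, c("REG", "REG", "REC_e", "RES_e"))
  expect_true(all(igraph::V(g)$eigencentrality >= 0 &
                    igraph::V(g)$eigencentrality <= 1))

  # same seed, same coordinates
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml2, format = "graphml", scores = scores,
                 layout_seed = 5)
  g2 <- igraph::read_graph(gml2, format = "graphml")
  expect_equal(igraph::V(g)$x, igraph::V(g2)$x)

  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_network(net, gexf, format = "gexf", layout_seed = 5)
  doc <- xml2::read_xml(gexf)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, ".//d1:node", ns), 4)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_length(edges, 3)
  expect_setequal(as.numeric(xml2::xml_attr(edges, "weight")), c(2, 5, 3))
})
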