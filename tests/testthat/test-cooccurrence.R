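test_that("expected co-occurrence follows N_i N_j / N", {
  expect_equal(expected_cooccurrence(3, 3, 5), 1.8)
  expect_equal(expected_cooccurrence(1, 1, 10), 0.1)
  expect_equal(expected_cooccurrence(10, 10, 10), 10)
  expect_error(expected_cooccurrence(1, 1, 0), "richness")
  expect_error(expected_cooccurrence(-1, 1, 5), "non-negative")
  expect_error(expected_cooccurrence(6, 1, 5), "exceed")
})

test_that("co-occurrence PMF matches the enumeration oracle on the spec fixtures", {
  # (3, 3, 5): minimum feasible overlap is 1 (pigeonhole)
  expect_equal(cooccurrence_pmf(3, 3, 5, 0), 0)
  expect_equal(cooccurrence_pmf(3, 3, 5, 1), 0.3)
  expect_equal(cooccurrence_pmf(3, 3, 5, 3), 0.1)
  expect_equal(cooccurrence_pmf(3, 3, 5, 0:3), enum_cooc_pmf(3, 3, 5)[1:4])
  pv <- cooccurrence_pvalues(3, 3, 5, 3)
  expect_equal(pv$p_gt, 0.1)
  expect_equal(cooccurrence_pvalues(3, 3, 5, 1)$p_lt, 0.3)
  # minimum feasible overlap has the whole upper tail
  expect_equal(cooccurrence_pvalues(3, 3, 5, 1)$p_gt, 1)
  expect_error(cooccurrence_pvalues(3, 3, 5, 0), "Infeasible")
})

test_that("PMF is normalised, symmetric, and has mean N_i N_j / N", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(1:200, 1)
    n_i <- sample(0:n, 1)
    n_j <- sample(0:n, 1)
    q <- 0:n
    pmf <- cooccurrence_pmf(n_i, n_j, n, q)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(sum(q * pmf), n_i * n_j / n, tolerance = 1e-10)
    expect_equal(pmf, cooccurrence_pmf(n_j, n_i, n, q), tolerance = 1e-12)
  }
})

test_that("pair scoring counts shared species on the community only", {
  traits <- make_test_traits()
  presence <- pool_plots(make_test_community())
  stats <- score_trait_pairs(presence, traits)

  # spot-check site A (sp1, sp3, sp4, sp5 present): mix & burrow
  a <- stats[stats$site == "A" & stats$modality_i == "mix" &
               stats$modality_j == "burrow", ]
  expect_equal(a$n, 4L)
  expect_equal(a$n_i, 3L) # sp1, sp4, sp5 bear mix
  expect_equal(a$n_j, 4L) # all four burrow
  expect_equal(a$q_obs, 3L)
  expect_equal(a$e, 3 * 4 / 4)

  # every pair statistic is symmetric under swapping i and j: recompute
  # from a column-reversed trait table
  rev_traits <- trait_matrix(
    as.data.frame(traits)[, c("taxon", rev(modalities(traits)$modality))],
    modalities(traits)[6:1, ]
  )
  stats_rev <- score_trait_pairs(presence, rev_traits)
  key <- function(s) {
    paste(s$site, pmin(s$modality_i, s$modality_j),
          pmax(s$modality_i, s$modality_j))
  }
  m <- match(key(stats), key(stats_rev))
  expect_false(anyNA(m))
  expect_equal(stats$q_obs, stats_rev$q_obs[m])
  expect_equal(stats$e, stats_rev$e[m])
  expect_equal(stats$p_gt, stats_rev$p_gt[m])

  # a taxon missing from the trait table is named in the error
  bad <- dplyr::bind_rows(
    tibble::as_tibble(presence),
    tibble::tibble(site = "A", treatment = "control", taxon = "ghost")
  )
  expect_error(score_trait_pairs(bad, traits), "ghost")
})

test_that("modalities borne by no community species yield no pairs", {
  traits <- make_test_traits()
  presence <- tibble::tibble(
    site = "A", treatment = "control", taxon = c("sp1", "sp5")
  )
  stats <- score_trait_pairs(presence, traits)
  # sp1 and sp5 both lack graze and surface
  expect_false(any(c(stats$modality_i, stats$modality_j) %in% c("graze", "surface")))
  # identical columns across the community give q_obs = n_i = n_j
  both <- stats[stats$modality_i == "mix" & stats$modality_j == "disperse", ]
  expect_equal(both$q_obs, 2L)
  expect_equal(both$n_i, 2L)
  expect_equal(both$n_j, 2L)
})

test_that("the filter drops pairs below one expected co-occurrence or unobserved", {
  stats <- tibble::tibble(
    site = "A", treatment = "control",
    modality_i = c("a", "a", "b"), modality_j = c("b", "c", "c"),
    n = 10L, n_i = c(4L, 2L, 3L), n_j = c(5L, 4L, 5L),
    q_obs = c(2L, 1L, 0L),
    e = c(2.0, 0.8, 1.5),
    p_lt = 0.5, p_gt = 0.5
  )
  kept <- filter_trait_pairs(stats)
  expect_equal(nrow(kept), 1)          # e = 0.8 dropped; q_obs = 0 dropped
  expect_equal(kept$modality_i, "a")
  expect_equal(kept$modality_j, "b")
  # optional significance filter tightens retention further
  expect_equal(nrow(filter_trait_pairs(stats, sig_level = 0.4)), 0)
  # within-trait exclusion
  traits <- make_test_traits()
  st <- score_trait_pairs(pool_plots(make_test_community()), traits)
  no_within <- filter_trait_pairs(st, e_threshold = 0,
                                  exclude_within_trait = TRUE, traits = traits)
  tr <- stats::setNames(modalities(traits)$trait, modalities(traits)$modality)
  expect_false(any(tr[no_within$modality_i] == tr[no_within$modality_j]))
})
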