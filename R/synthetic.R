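# Synthetic-data generator: a seeded emulation of a multi-site nutrient
# enrichment field design. Each site carries a latent complexity u in [0,1]
# driving richness and trait redundancy of its control community; enrichment
# removes species at a level-dependent rate whose site-to-site variability
# shrinks with u.

#' Generator configuration
#'
#' Bundles every knob of the synthetic dataset: the experimental design
#' (24 sites x control/medium/high x 3 plots), the species pool and trait
#' structure, the cross-site complexity gradient, and the stress model.
#' All randomness flows from `seed`.
#'
#' @param seed Integer seed; the whole dataset is reproducible from
#'   `(config, seed)`.
#' @param n_sites Number of sites (default 24).
#' @param treatments Treatment levels; first is the control.
#' @param n_plots Plots per site-treatment (default 3).
#' @param richness_range Min/max taxa per site (default 19–48); control
#'   richness interpolates across it with latent complexity `u`.
#' @param n_species Size of the regional species pool (default 140).
#' @param modality_counts Named counts of modalities per trait category.
#' @param redundancy Non-negative; scales how many species share a modality.
#'   At 0 each modality pair is shared by at most one species pool-wide in
#'   expectation; larger values make pairs (and hence network edges) more
#'   redundant. Default 2.5.
#' @param generalist_bias Strength of high-`u` sites' preference for
#'   modality-rich species, steepening the complexity gradient. Default 1.
#' @param loss_medium,loss_high Baseline per-species loss probability under
#'   medium/high enrichment (defaults 0.12 / 0.35).
#' @param gain_medium Probability that a pool species absent from the
#'   control colonises a medium plot — the opportunist term letting medium
#'   enrichment sometimes enhance networks. Default 0.06.
#' @param res_i_boost Multiplier on loss probability for species bearing a
#'   resistance-inhibiting (`RES_i`) modality. Default 2.
#' @param sigma0 Site-level lognormal noise scale on the loss rate at
#'   `u = 0`. Default 0.8.
#' @param variance_decay In `[0, 1]`: how strongly the loss-rate noise
#'   shrinks with `u` (`sigma(u) = sigma0 (1 - variance_decay * u)`).
#'   Set 0 for a homoscedastic stress response. Default 0.85.
#' @param plot_detect Probability a community species is caught in any one
#'   plot core (plots are unioned downstream). Default 0.85.
#' @param mean_abund Mean count of a detected species in a plot. Default 4.
#' @return A `nat_config` list.
#' @export
nat_config <- function(seed = 1L,
                       n_sites = 24L,
                       treatments = c("control", "medium", "high"),
                       n_plots = 3L,
                       richness_range = c(19L, 48L),
                       n_species = 140L,
                       modality_counts = c(REG = 8L, REC_e = 5L, REC_i = 4L,
                                           RES_e = 5L, RES_i = 4L),
                       redundancy = 2.5,
                       generalist_bias = 1,
                       loss_medium = 0.12,
                       loss_high = 0.35,
                       gain_medium = 0.06,
                       res_i_boost = 2,
                       sigma0 = 0.8,
                       variance_decay = 0.85,
                       plot_detect = 0.85,
                       mean_abund = 4) {
  stopifnot(
    n_sites >= 1, n_plots >= 1, n_species >= 1,
    length(richness_range) == 2, richness_range[1] >= 1,
    richness_range[2] >= richness_range[1],
    all(names(modality_counts) %in% TRAIT_CATEGORIES),
    all(modality_counts >= 1),
    redundancy >= 0, generalist_bias >= 0,
    loss_medium >= 0, loss_medium <= 1, loss_high >= 0, loss_high <= 1,
    gain_medium >= 0, gain_medium <= 1, res_i_boost >= 0,
    sigma0 >= 0, variance_decay >= 0, variance_decay <= 1,
    plot_detect > 0, plot_detect <= 1, mean_abund > 0,
    identical(treatments[1], "control")
  )
  structure(
    list(
      seed = as.integer(seed), n_sites = as.integer(n_sites),
      treatments = treatments, n_plots = as.integer(n_plots),
      richness_range = as.integer(richness_range),
      n_species = as.integer(n_species), modality_counts = modality_counts,
      redundancy = redundancy, generalist_bias = generalist_bias,
      loss_medium = loss_medium, loss_high = loss_high,
      gain_medium = gain_medium, res_i_boost = res_i_boost,
      sigma0 = sigma0, variance_decay = variance_decay,
      plot_detect = plot_detect, mean_abund = mean_abund
    ),
    class = "nat_config"
  )
}

#' Read a generator / pipeline configuration from YAML
#'
#' Keys mirror the arguments of [nat_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `nat_config`.
#' @export
read_nat_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(nat_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$modality_counts)) {
    vals$modality_counts <- unlist(vals$modality_counts)
  }
  do.call(nat_config, vals)
}

#' Generate a synthetic trait table
#'
#' Draws a regional species pool where each species bears each modality
#' independently, with the per-category probability set so a modality pair
#' is expected to be shared by `1 + redundancy` pool species. Every species
#' is guaranteed at least one ecosystem-regulating (REG) modality and at
#' least one modality overall.
#'
#' @param config A [nat_config()].
#' @return A binary [trait_matrix()] of `n_species` taxa.
#' @export
generate_trait_table <- function(config) {
  stopifnot(inherits(config, "nat_config"))
  withr::with_seed(config$seed, generate_trait_table_impl(config))
}

generate_trait_table_impl <- function(config) {
  counts <- config$modality_counts
  mods <- tibble(
    modality = unlist(purrr::imap(counts, function(k, cat) {
      sprintf("%s_m%02d", tolower(gsub("_", "", cat)), seq_len(k))
    })),
    trait = NA_character_,
    category = rep(names(counts), counts)
  )
  # parent traits: modalities grouped in pairs within a category
  mods$trait <- paste0(
    tolower(gsub("_", "", mods$category)), "_t",
    unlist(purrr::map(counts, ~ rep(seq_len(ceiling(.x / 2)), each = 2)[seq_len(.x)]))
  )
  n_sp <- config$n_species
  # bearing probability: expected pool species sharing a cross-category
  # pair is n_sp * p^2 = 1 + redundancy
  p <- min(sqrt((1 + config$redundancy) / n_sp), 0.9)
  m <- matrix(rbinom(n_sp * nrow(mods), 1, p), nrow = n_sp)
  colnames(m) <- mods$modality
  reg_cols <- which(mods$category == "REG")
  for (s in seq_len(n_sp)) {
    if (sum(m[s, reg_cols]) == 0) { # force >= 1 REG modality
      m[s, sample(reg_cols, 1)] <- 1
    }
  }
  scores <- as_tibble(as.data.frame(m)) %>%
    mutate(taxon = sprintf("sp%03d", seq_len(n_sp)), .before = 1)
  trait_matrix(scores, mods, binary = TRUE)
}

#' Generate synthetic community data
#'
#' Control communities sample the species pool with richness and a
#' generalist bias increasing in the site's latent complexity `u`; medium
#' and high treatments are derived from the site's control species set by
#' Bernoulli species loss with probability rising with enrichment level,
#' boosted for `RES_i`-bearing species, multiplied by a site-level
#' lognormal factor whose scale decays with `u` (so complex sites respond
#' less variably), and — at medium level — opportunistic colonisation that
#' sometimes enhances the community. Counts are laid out over `n_plots`
#' plots per site-treatment with per-plot detection and Poisson abundances.
#'
#' @param config A [nat_config()].
#' @param traits Trait table from [generate_trait_table()]; regenerated
#'   from `config` when omitted.
#' @return Community records (see [validate_community()]) with attributes
#'   `truth` (per-site tibble of latent values) and `covariates` (per-site
#'   PAR decreasing in `u`, porewater NH4 increasing in `u`).
#' @export
generate_communities <- function(config, traits = NULL) {
  stopifnot(inherits(config, "nat_config"))
  if (is.null(traits)) traits <- generate_trait_table(config)
  # distinct stream from the trait draw so the pool is stable across calls
  withr::with_seed(config$seed + 1000003L, {
    generate_communities_impl(config, traits)
  })
}

generate_communities_impl <- function(config, traits) {
  n_sites <- config$n_sites
  sites <- sprintf("site%02d", seq_len(n_sites))
  u <- runif(n_sites)
  mods <- modalities(traits)
  scores <- trait_scores(traits)
  res_i_bearer <- rowSums(scores[, mods$modality[mods$category == "RES_i"],
                                 drop = FALSE]) > 0
  n_modal <- rowSums(scores)
  z_modal <- as.numeric(scale(n_modal))
  r_lo <- config$richness_range[1]; r_hi <- config$richness_range[2]
  records <- list()
  truth <- list()
  for (s in seq_len(n_sites)) {
    richness <- round(r_lo + u[s] * (r_hi - r_lo))
    richness <- max(r_lo, min(r_hi, richness))
    w <- exp(config$generalist_bias * u[s] * z_modal)
    control_taxa <- sample(traits$taxon, richness, prob = w)
    loss_real <- c(control = 0)
    for (trt in config$treatments) {
      if (trt == "control") {
        taxa <- control_taxa
      } else {
        base <- if (trt == "medium") config$loss_medium else config$loss_high
        sigma <- config$sigma0 * (1 - config$variance_decay * u[s])
        site_mult <- exp(rnorm(1, mean = -sigma^2 / 2, sd = sigma))
        idx <- match(control_taxa, traits$taxon)
        q <- pmin(base * site_mult *
                    ifelse(res_i_bearer[idx], config$res_i_boost, 1), 1)
        lost <- rbinom(length(control_taxa), 1, q) == 1
        taxa <- control_taxa[!lost]
        if (trt == "medium" && config$gain_medium > 0) {
          # opportunist colonisation scaled to community size: expected
          # gains are gain_medium * richness regardless of pool size
          pool_rest <- setdiff(traits$taxon, control_taxa)
          p_gain <- min(config$gain_medium * site_mult *
                          length(control_taxa) / max(length(pool_rest), 1), 1)
          gained <- pool_rest[rbinom(length(pool_rest), 1, p_gain) == 1]
          taxa <- c(taxa, gained)
        }
        loss_real[trt] <- 1 - sum(control_taxa %in% taxa) / length(control_taxa)
      }
      # lay species out over plots; ensure each survives in >= 1 plot so
      # the pooled (unioned) community equals the drawn species set
      for (taxon in taxa) {
        present <- rbinom(config$n_plots, 1, config$plot_detect)
        if (sum(present) == 0) present[sample(config$n_plots, 1)] <- 1
        cnt <- ifelse(present == 1,
                      rpois(config$n_plots, config$mean_abund - 1) + 1, 0)
        keep <- cnt > 0
        records[[length(records) + 1]] <- tibble(
          site = sites[s], treatment = trt,
          plot = sprintf("plot%d", seq_len(config$n_plots))[keep],
          taxon = taxon, count = as.integer(cnt[keep])
        )
      }
      if (length(taxa) == 0) {
        # the plots were sampled and held nothing: record the empty
        # community explicitly so it stays part of the crossed design
        records[[length(records) + 1]] <- tibble(
          site = sites[s], treatment = trt, plot = "plot1",
          taxon = control_taxa[1], count = 0L
        )
      }
    }
    truth[[s]] <- tibble(
      site = sites[s], u = u[s], control_richness = length(control_taxa),
      loss_medium = unname(loss_real["medium"]),
      loss_high = unname(loss_real["high"])
    )
  }
  community <- bind_rows(records) %>% validate_community()
  truth <- bind_rows(truth)
  covariates <- tibble(
    site = sites,
    mean_par = 900 - 600 * u + rnorm(n_sites, sd = 60),
    porewater_nh4 = exp(1.5 + 2 * u + rnorm(n_sites, sd = 0.3))
  )
  structure(community, truth = truth, covariates = covariates)
}

#' Generate a full synthetic dataset
#'
#' @param config A [nat_config()].
#' @return A list with `traits` (binary [trait_matrix()]), `community`
#'   (long-form records), `truth` (per-site latent complexity `u`, realised
#'   control richness, realised loss fractions), and `covariates` (per-site
#'   PAR and porewater NH4).
#' @export
generate_dataset <- function(config) {
  traits <- generate_trait_table(config)
  community <- generate_communities(config, traits)
  list(
    traits = traits,
    community = as_tibble(community),
    truth = attr(community, "truth"),
    covariates = attr(community, "covariates")
  )
}
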