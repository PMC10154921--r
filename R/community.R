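#' Validate long-form community data
#'
#' Community data are long-form records of `(site, treatment, plot, taxon,
#' count)`: the abundance of each taxon in each plot of each site-treatment.
#' Counts are non-negative integers, treatments are exactly
#' `control`/`medium`/`high`, and each `(site, treatment, plot, taxon)`
#' combination appears at most once.
#'
#' @param community A data frame with columns `site`, `treatment`, `plot`,
#'   `taxon`, `count`.
#' @return The validated data as a tibble (columns coerced to character /
#'   integer), invisibly usable in a pipe.
#' @export
validate_community <- function(community) {
  community <- as_tibble(community)
  need <- c("site", "treatment", "plot", "taxon", "count")
  missing_cols <- setdiff(need, names(community))
  if (length(missing_cols) > 0) {
    abort(paste0("Community data lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  community <- community %>%
    mutate(
      site = as.character(.data$site),
      treatment = as.character(.data$treatment),
      plot = as.character(.data$plot),
      taxon = as.character(.data$taxon)
    )
  bad_trt <- setdiff(unique(community$treatment), TREATMENT_LEVELS)
  if (length(bad_trt) > 0) {
    abort(paste0(
      'Unknown treatment value(s): ', paste0('"', bad_trt, '"', collapse = ", "),
      '. Treatments must be "control", "medium" or "high".'
    ))
  }
  cnt <- community$count
  if (!is.numeric(cnt) || anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt))) {
    abort("`count` must be non-negative integers with no missing values.")
  }
  community$count <- as.integer(cnt)
  dup <- community %>%
    count(.data$site, .data$treatment, .data$plot, .data$taxon) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (site, treatment, plot, taxon) record(s), first: ",
      paste(dup$site[1], dup$treatment[1], dup$plot[1], dup$taxon[1], sep = "/")
    ))
  }
  community[, need]
}

#' Read long-form community data from CSV
#'
#' @param path CSV with columns `site`, `treatment`, `plot`, `taxon`, `count`.
#' @return A validated tibble (see [validate_community()]).
#' @export
read_community <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      site = readr::col_character(), treatment = readr::col_character(),
      plot = readr::col_character(), taxon = readr::col_character(),
      count = readr::col_integer()
    ),
    progress = FALSE
  ) %>%
    validate_community()
}

#' Write long-form community data to CSV
#'
#' @param community Community records (validated on the way out).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(community, path) {
  readr::write_csv(validate_community(community), path, progress = FALSE)
  invisible(path)
}

#' Pool plots into site-treatment communities
#'
#' Each site-treatment's species list is the union of its plots: a taxon is
#' present when its summed count over the treatment's plots is positive. This
#' yields one community (and later one network) per site and treatment.
#'
#' @param community Long-form community records (see [validate_community()]).
#' @param site,treatment Optional filters; by default all site-treatments
#'   present in the data are pooled. Requesting a site or treatment absent
#'   from the data is an error.
#' @return A tibble of presence records with columns `site`, `treatment`,
#'   `taxon` — one row per species present in the pooled community.
#'   Site-treatments whose counts are all zero yield no rows but are listed
#'   in the `"communities"` attribute, a tibble of `(site, treatment, n_taxa)`
#'   covering every pooled community including empty ones.
#' @export
pool_plots <- function(community, site = NULL, treatment = NULL) {
  community <- validate_community(community)
  if (!is.null(site)) {
    unknown <- setdiff(site, unique(community$site))
    if (length(unknown) > 0) {
      abort(paste0("Unknown site(s): ", paste(unknown, collapse = ", ")))
    }
    community <- community %>% filter(.data$site %in% !!site)
  }
  if (!is.null(treatment)) {
    unknown <- setdiff(treatment, unique(community$treatment))
    if (length(unknown) > 0) {
      abort(paste0("Unknown treatment(s): ", paste(unknown, collapse = ", ")))
    }
    community <- community %>% filter(.data$treatment %in% !!treatment)
  }
  pooled <- community %>%
    group_by(.data$site, .data$treatment, .data$taxon) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  presence <- pooled %>%
    filter(.data$count > 0) %>%
    select("site", "treatment", "taxon") %>%
    arrange(.data$site, .data$treatment, .data$taxon)
  # a site-treatment whose records are all zero counts is an empty
  # community with N = 0, not a missing one
  sizes <- pooled %>%
    group_by(.data$site, .data$treatment) %>%
    summarise(n_taxa = sum(.data$count > 0), .groups = "drop") %>%
    arrange(.data$site, .data$treatment)
  structure(presence, communities = sizes,
            class = c("pooled_community", class(presence)))
}

#' Community sizes of pooled presence records
#'
#' @param presence Output of [pool_plots()].
#' @return Tibble `(site, treatment, n_taxa)`, one row per pooled community
#'   (including empty ones).
#' @export
community_sizes <- function(presence) {
  sizes <- attr(presence, "communities")
  if (is.null(sizes)) {
    sizes <- as_tibble(presence) %>%
      group_by(.data$site, .data$treatment) %>%
      summarise(n_taxa = dplyr::n_distinct(.data$taxon), .groups = "drop")
  }
  sizes
}
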