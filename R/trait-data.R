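#' Construct a trait matrix
#'
#' A trait matrix holds taxa-by-modality scores together with the modality
#' metadata (parent trait and category). It is a tibble with one row per
#' taxon, a `taxon` column, and one numeric column per trait modality;
#' modality metadata travel in the `"modalities"` attribute and a `"binary"`
#' attribute records whether scores have been reduced to presence/absence.
#'
#' @param scores A data frame with a `taxon` column and one non-negative
#'   numeric column per modality.
#' @param modalities A data frame with columns `modality`, `trait`, and
#'   `category`; `category` must be one of `REG`, `REC_e`, `REC_i`, `RES_e`,
#'   `RES_i`. One row per score column.
#' @param binary Logical; set when all scores are already 0/1.
#' @return A `trait_matrix` tibble.
#' @examples
#' scores <- data.frame(taxon = c("sp1", "sp2"), burrower = c(1, 0), grazer = c(0, 1))
#' mods <- data.frame(
#'   modality = c("burrower", "grazer"),
#'   trait = c("mobility", "feeding"),
#'   category = c("REG", "REC_e")
#' )
#' trait_matrix(scores, mods)
#' @export
trait_matrix <- function(scores, modalities, binary = NULL) {
  scores <- as_tibble(scores)
  modalities <- as_tibble(modalities)
  if (!"taxon" %in% names(scores)) {
    abort("`scores` must have a `taxon` column.")
  }
  if (!all(c("modality", "trait", "category") %in% names(modalities))) {
    abort("`modalities` must have columns `modality`, `trait`, `category`.")
  }
  modalities <- modalities %>%
    mutate(across(dplyr::all_of(c("modality", "trait", "category")), as.character))
  bad_cat <- setdiff(unique(modalities$category), TRAIT_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(paste0(
      "Unknown trait categor", if (length(bad_cat) > 1) "ies: " else "y: ",
      paste0('"', bad_cat, '"', collapse = ", "),
      ". Valid categories are ", paste(TRAIT_CATEGORIES, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(modalities$modality)) {
    abort("Duplicate modality ids in `modalities`.")
  }
  score_cols <- setdiff(names(scores), "taxon")
  if (!setequal(score_cols, modalities$modality)) {
    abort("Score columns and `modalities$modality` must name the same set of modalities.")
  }
  scores <- scores[, c("taxon", modalities$modality)]
  scores$taxon <- as.character(scores$taxon)
  if (anyDuplicated(scores$taxon)) {
    abort(paste0(
      "Duplicate taxon name(s): ",
      paste(unique(scores$taxon[duplicated(scores$taxon)]), collapse = ", ")
    ))
  }
  mat <- as.matrix(scores[, modalities$modality, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat) || any(mat < 0)) {
    abort("Trait scores must be non-negative numbers with no missing values.")
  }
  if (nrow(scores) > 0 && any(rowSums(mat) == 0)) {
    warn(paste0(
      "Taxa with no nonzero trait score: ",
      paste(scores$taxon[rowSums(mat) == 0], collapse = ", ")
    ))
  }
  if (is.null(binary)) binary <- all(mat %in% c(0, 1))
  if (binary && !all(mat %in% c(0, 1))) {
    abort("`binary = TRUE` but scores are not all 0/1.")
  }
  structure(
    scores,
    modalities = modalities,
    binary = binary,
    class = c("trait_matrix", class(tibble()))
  )
}

#' Modality metadata of a trait matrix
#'
#' @param traits A [trait_matrix()].
#' @return A tibble with columns `modality`, `trait`, `category`.
#' @export
modalities <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  attr(traits, "modalities")
}

#' Is a trait matrix binary?
#'
#' @param traits A [trait_matrix()].
#' @return `TRUE` if all scores are presence/absence.
#' @export
is_binary <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  isTRUE(attr(traits, "binary"))
}

#' @export
print.trait_matrix <- function(x, ...) {
  mods <- attr(x, "modalities")
  cat(sprintf(
    "<trait_matrix> %d taxa x %d modalities (%s)\n",
    nrow(x), nrow(mods), if (is_binary(x)) "binary" else "fuzzy-coded"
  ))
  cat("categories:", paste(sprintf(
    "%s=%d", TRAIT_CATEGORIES,
    vapply(TRAIT_CATEGORIES, function(k) sum(mods$category == k), integer(1))
  ), collapse = " "), "\n")
  NextMethod()
}

# score matrix (taxa x modalities) with taxon rownames
trait_scores <- function(traits) {
  m <- as.matrix(as.data.frame(traits)[, modalities(traits)$modality, drop = FALSE])
  rownames(m) <- traits$taxon
  m
}

#' Read a trait table from CSV
#'
#' The expected dialect has taxa in rows and modalities in columns. The first
#' column is `taxon`; one metadata row whose taxon field is `#category`
#' assigns each modality its category, and an optional `#trait` row assigns
#' the parent trait (defaults to the modality id).
#'
#' @param path Path to a CSV file.
#' @return A [trait_matrix()].
#' @seealso [write_trait_table()] for the inverse.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "taxon") {
    abort("First column of a trait table must be `taxon`.")
  }
  meta_rows <- grepl("^#", raw$taxon)
  meta <- raw[meta_rows, , drop = FALSE]
  body <- raw[!meta_rows, , drop = FALSE]
  cat_row <- meta[meta$taxon == "#category", , drop = FALSE]
  if (nrow(cat_row) != 1) {
    abort("Trait table must contain exactly one `#category` metadata row.")
  }
  trait_row <- meta[meta$taxon == "#trait", , drop = FALSE]
  mod_ids <- setdiff(names(raw), "taxon")
  mods <- tibble(
    modality = mod_ids,
    trait = if (nrow(trait_row) == 1) as.character(trait_row[1, mod_ids]) else mod_ids,
    category = as.character(cat_row[1, mod_ids])
  )
  scores <- body %>%
    mutate(across(dplyr::all_of(mod_ids), as.numeric))
  trait_matrix(scores, mods)
}

#' Write a trait table to CSV
#'
#' Writes the dialect [read_trait_table()] reads (a `#category` and a
#' `#trait` metadata row above the taxon rows).
#'
#' @param traits A [trait_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(inherits(traits, "trait_matrix"))
  mods <- modalities(traits)
  header <- tibble(taxon = c("#category", "#trait"))
  for (i in seq_len(nrow(mods))) {
    header[[mods$modality[i]]] <- c(mods$category[i], mods$trait[i])
  }
  body <- as_tibble(as.data.frame(traits)) %>%
    mutate(across(-"taxon", as.character))
  readr::write_csv(bind_rows(header, body), path, progress = FALSE)
  invisible(path)
}

#' Binarize fuzzy-coded trait scores
#'
#' Converts fuzzy-coded scores to presence/absence: a taxon bears a modality
#' when its score exceeds `threshold`. Idempotent for any fixed threshold on
#' already-binary data with `threshold = 0`.
#'
#' @param traits A [trait_matrix()].
#' @param threshold Non-negative cutoff; scores strictly greater than it
#'   become 1, all others 0. Default 0 (any positive score counts).
#' @return A binary [trait_matrix()].
#' @export
binarize_traits <- function(traits, threshold = 0) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("`threshold` must be a single non-negative number.")
  }
  mods <- modalities(traits)
  out <- as_tibble(as.data.frame(traits)) %>%
    mutate(across(dplyr::all_of(mods$modality), ~ as.numeric(.x > threshold)))
  trait_matrix(out, mods, binary = TRUE)
}
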