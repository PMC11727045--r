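# Tabular formats: band matrices, trait tables, Q matrices, ln P(D)
# replicate tables. All TSV, UTF-8, "NA" for missing.

#' Read a binary band-presence matrix
#'
#' The file must be tab-separated with a two-column key (`marker_id`,
#' `band_id`) followed by one column per individual; cells are 0, 1 or NA.
#' Any other cell value is an error naming the offending cell.
#'
#' @param path Path to a TSV file.
#' @return A `band_matrix`: tibble with key columns `marker_id`, `band_id`
#'   and one 0/1/NA integer column per individual.
#' @export
read_band_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    band_id = readr::col_character(),
    .default = readr::col_character()
  ), na = "NA", progress = FALSE)
  assert_cols(x, c("marker_id", "band_id"), "band matrix")
  ind_cols <- setdiff(names(x), c("marker_id", "band_id"))
  for (col in ind_cols) {
    vals <- x[[col]]
    bad <- which(!is.na(vals) & !vals %in% c("0", "1"))
    if (length(bad)) {
      abort(sprintf(
        "non-binary band cell at marker '%s', band '%s', individual '%s': '%s'",
        x$marker_id[bad[1]], x$band_id[bad[1]], col, vals[bad[1]]))
    }
    x[[col]] <- as.integer(vals)
  }
  validate_band_matrix(x)
}

#' Write a band matrix to TSV
#'
#' @param bands A `band_matrix` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(bands, path) {
  validate_band_matrix(bands)
  readr::write_tsv(bands, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Validate a band matrix
#'
#' Checks the key columns, that scores are 0/1/NA, that every marker has at
#' least one band, and that an individual is missing for a marker iff all
#' of that marker's bands are missing.
#'
#' @param bands Candidate band matrix tibble.
#' @return The validated tibble (class `band_matrix` added), invisibly
#'   usable in pipes.
#' @export
validate_band_matrix <- function(bands) {
  assert_cols(bands, c("marker_id", "band_id"), "band matrix")
  ind_cols <- band_individuals(bands)
  if (length(ind_cols) == 0L) abort("band matrix has no individual columns")
  m <- as.matrix(bands[ind_cols])
  if (!all(m %in% c(0L, 1L, NA_integer_))) {
    abort("band matrix scores must be 0, 1 or NA")
  }
  if (any(table(bands$marker_id) < 1L)) abort("every marker needs >= 1 band")
  # NA must be all-or-nothing within a marker for a given individual
  by_marker <- split(seq_len(nrow(bands)), bands$marker_id)
  for (rows in by_marker) {
    sub <- m[rows, , drop = FALSE]
    na_frac <- colMeans(is.na(sub))
    if (any(na_frac > 0 & na_frac < 1)) {
      abort(sprintf(
        "marker '%s': individuals must be NA for all bands or none",
        bands$marker_id[rows[1]]))
    }
  }
  class(bands) <- unique(c("band_matrix", class(bands)))
  bands
}

#' Individual IDs of a band matrix
#'
#' @param bands A band matrix tibble.
#' @return Character vector of individual column names.
#' @export
band_individuals <- function(bands) {
  setdiff(names(bands), c("marker_id", "band_id"))
}

#' Read a long-format phenotype table
#'
#' Expected columns: `individual_id`, `trait`, `year`, `value` (numeric or
#' NA).
#'
#' @param path Path to a TSV file.
#' @return Tibble of trait observations.
#' @export
read_trait_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    trait = readr::col_character(),
    year = readr::col_integer(),
    value = readr::col_double()
  ), na = "NA", progress = FALSE)
  assert_cols(x, c("individual_id", "trait", "year", "value"), "trait table")
  x
}

#' Read an admixture (Q) matrix
#'
#' First column `individual_id`, remaining columns group proportions; each
#' row must sum to 1 within 1e-6.
#'
#' @param path Path to a TSV file.
#' @return Tibble with `individual_id` and one column per group.
#' @export
read_q_matrix <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  assert_cols(x, "individual_id", "Q matrix")
  q <- as.matrix(x[setdiff(names(x), "individual_id")])
  if (any(q < 0 | q > 1) || any(abs(rowSums(q) - 1) > 1e-6)) {
    abort("Q matrix rows must be proportions summing to 1 (tolerance 1e-6)")
  }
  x
}

#' Read a STRUCTURE-style ln P(D) replicate table
#'
#' Expected columns: `K` (integer), `rep` (replicate index), `lnp` (log
#' probability of the data).
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `K`, `rep`, `lnp`.
#' @export
read_lnp_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    K = readr::col_integer(),
    rep = readr::col_integer(),
    lnp = readr::col_double()
  ), na = "NA", progress = FALSE)
  assert_cols(x, c("K", "rep", "lnp"), "lnP(D) table")
  x
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are kept and the string is ";"-terminated. Read back with
#' [ape::read.tree()]; the round trip preserves topology and lengths.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
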