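# Per-marker allele statistics from binary band matrices: Na, Ne, Ho, He,
# PIC and Shannon's I under a codominant reading of band patterns.

#' Codominant genotypes from band patterns
#'
#' An individual with exactly one present band at a marker is read as
#' homozygous for that band-allele; two present bands as heterozygous; zero
#' or more than two present bands (or any NA) as missing.
#'
#' @param bands A `band_matrix` tibble.
#' @param marker Optional single marker ID; default all markers.
#' @return Long tibble `marker_id`, `individual_id`, `allele1`, `allele2`
#'   (band IDs; both NA when missing).
#' @export
bands_to_genotypes <- function(bands, marker = NULL) {
  bands <- validate_band_matrix(bands)
  if (!is.null(marker)) {
    bands <- bands[bands$marker_id %in% marker, , drop = FALSE]
    if (nrow(bands) == 0L) abort(sprintf("marker '%s' not present", marker))
  }
  inds <- band_individuals(bands)
  out <- lapply(split(seq_len(nrow(bands)), bands$marker_id), function(rows) {
    sub <- as.matrix(bands[rows, inds, drop = FALSE])
    ids <- bands$band_id[rows]
    geno <- lapply(seq_along(inds), function(j) {
      v <- sub[, j]
      if (anyNA(v)) return(c(NA_character_, NA_character_))
      present <- ids[v == 1L]
      if (length(present) == 1L) c(present, present)
      else if (length(present) == 2L) sort(present)
      else c(NA_character_, NA_character_)
    })
    geno <- do.call(rbind, geno)
    tibble(marker_id = bands$marker_id[rows[1]], individual_id = inds,
           allele1 = geno[, 1], allele2 = geno[, 2])
  })
  dplyr::bind_rows(out)
}

#' Allele frequencies from codominant genotypes
#'
#' `p_i` = allele count / (2 x non-missing individuals), so frequencies sum
#' to 1 per marker. Markers with no scorable genotype are skipped with a
#' warning.
#'
#' @param genotypes Output of [bands_to_genotypes()].
#' @return Tibble `marker_id`, `allele`, `freq`.
#' @export
allele_frequencies <- function(genotypes) {
  assert_cols(genotypes, c("marker_id", "individual_id", "allele1", "allele2"))
  ok <- !is.na(genotypes$allele1)
  skipped <- setdiff(unique(genotypes$marker_id),
                     unique(genotypes$marker_id[ok]))
  if (length(skipped)) {
    warn(sprintf("%d marker(s) with no scorable genotype skipped: %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  genotypes[ok, ] |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::count(.data$marker_id, .data$allele, name = "n") |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("marker_id", "allele", "freq")
}

# Closed-form statistics from one frequency vector.
freq_stats <- function(p) {
  p <- p[p > 0]
  sum_p2 <- sum(p^2)
  het <- 1 - sum_p2
  # PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2
  #     = 1 - sum p_i^2 - ((sum p_i^2)^2 - sum p_i^4)
  pic <- het - (sum_p2^2 - sum(p^4))
  c(Na = length(p), Ne = 1 / sum_p2, He = het, PIC = pic,
    I = -sum(p * log(p)))
}

#' Per-marker allele statistics and panel summary
#'
#' Computes, for every marker with at least one scorable genotype: observed
#' allele count (Na), effective allele count (Ne = 1 / sum p^2), observed
#' heterozygosity (Ho, fraction of heterozygous scorable individuals),
#' expected heterozygosity (He = 1 - sum p^2, uncorrected), polymorphism
#' information content (PIC = 1 - sum p^2 - sum_{i<j} 2 p_i^2 p_j^2) and
#' Shannon's diversity index (I = -sum p ln p). The panel summary holds
#' unweighted means across markers and the fractions of markers with
#' PIC > 0.5 and PIC > 0.25.
#'
#' @param bands A `band_matrix` tibble.
#' @param unbiased_he If `TRUE`, multiply He by `2N/(2N-1)` (small-sample
#'   correction; off by default).
#' @return Tibble of class `marker_stats` (`marker_id`, `n_scored`, `Na`,
#'   `Ne`, `Ho`, `He`, `PIC`, `I`) with a `panel` attribute; see
#'   [glance.marker_stats()].
#' @export
marker_summary <- function(bands, unbiased_he = FALSE) {
  geno <- bands_to_genotypes(bands)
  freqs <- allele_frequencies(geno)
  ho <- geno |>
    dplyr::filter(!is.na(.data$allele1)) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(n_scored = dplyr::n(),
                     Ho = mean(.data$allele1 != .data$allele2),
                     .groups = "drop")
  stats <- freqs |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(stats = list(freq_stats(.data$freq)), .groups = "drop") |>
    tidyr::unnest_wider("stats")
  res <- dplyr::inner_join(ho, stats, by = "marker_id")
  if (unbiased_he) {
    res$He <- res$He * (2 * res$n_scored) / (2 * res$n_scored - 1)
  }
  res <- dplyr::select(res, "marker_id", "n_scored", "Na", "Ne", "Ho",
                       "He", "PIC", "I")
  panel <- tibble(
    n_markers = nrow(res),
    mean_Na = mean(res$Na), mean_Ne = mean(res$Ne),
    mean_Ho = mean(res$Ho), mean_He = mean(res$He),
    mean_PIC = mean(res$PIC), mean_I = mean(res$I),
    frac_pic_gt_0.5 = mean(res$PIC > 0.5),
    frac_pic_gt_0.25 = mean(res$PIC > 0.25)
  )
  structure(res, panel = panel, class = c("marker_stats", class(res)))
}

#' @rdname marker_summary
#' @param x A `marker_stats` object.
#' @param ... Unused.
#' @export
glance.marker_stats <- function(x, ...) {
  attr(x, "panel")
}
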