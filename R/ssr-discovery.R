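# MISA-style perfect/compound SSR detection and InDel-SSR co-localization.
#
# A perfect SSR is a maximal tandem run of a primitive 1-6 bp motif meeting
# a per-motif-length repeat threshold. Runs never cross N, a tract is
# reported once at the smallest qualifying motif length (primitive motifs
# only), partial trailing copies are trimmed, and the leftmost phase wins.

#' SSR search parameters
#'
#' Defaults follow the standard MISA configuration for marker development:
#' at least 10 copies for mononucleotide motifs, 5 for dinucleotide, 4 for
#' tri- through hexanucleotide motifs; two tracts separated by fewer than
#' 100 bp form a compound locus; InDel flanks are 500 bp each side.
#'
#' @param min_repeats Named integer vector, minimum copy number per motif
#'   length `"1"`..`"6"`.
#' @param compound_max_gap Tracts closer than this many bp merge into a
#'   compound locus (strict inequality).
#' @param flank_size Flank length (bp) on each side of an InDel anchor.
#' @return An `ssr_params` list.
#' @export
ssr_params <- function(min_repeats = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                       `4` = 4L, `5` = 4L, `6` = 4L),
                       compound_max_gap = 100L,
                       flank_size = 500L) {
  min_repeats <- as.integer(min_repeats[as.character(1:6)])
  names(min_repeats) <- as.character(1:6)
  if (anyNA(min_repeats) || any(min_repeats < 2L)) {
    abort("min_repeats must give a threshold >= 2 for every motif length 1..6")
  }
  if (compound_max_gap < 0L) abort("compound_max_gap must be >= 0")
  if (flank_size < 0L) abort("flank_size must be >= 0")
  structure(list(min_repeats = min_repeats,
                 compound_max_gap = as.integer(compound_max_gap),
                 flank_size = as.integer(flank_size)),
            class = "ssr_params")
}

# Scan one sequence (character scalar) for perfect SSRs. Returns 1-based
# inclusive coordinates relative to the sequence start.
scan_perfect_ssrs <- function(seq, params) {
  n <- nchar(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  valid <- s %in% c("A", "C", "G", "T")
  out <- vector("list", 6L)
  for (L in 1:6) {
    thr <- params$min_repeats[[as.character(L)]]
    if (n < L * thr) next
    i1 <- seq_len(n - L)
    m <- s[i1] == s[i1 + L] & valid[i1] & valid[i1 + L]
    r <- rle(m)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    hits <- which(r$values & r$lengths >= L * (thr - 1L))
    if (!length(hits)) next
    starts <- run_start[hits]
    k <- (r$lengths[hits] + L) %/% L
    keep <- k >= thr
    if (!any(keep)) next
    starts <- starts[keep]; k <- k[keep]
    motifs <- substr(rep(seq, length(starts)), starts, starts + L - 1L)
    prim <- vapply(motifs, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    if (!any(prim)) next
    starts <- starts[prim]; k <- k[prim]; motifs <- motifs[prim]
    out[[L]] <- tibble(
      start = starts,
      end = starts + k * L - 1L,
      motif = motifs,
      motif_len = L,
      n_repeats = k
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(start = integer(), end = integer(), motif = character(),
                  motif_len = integer(), n_repeats = integer()))
  }
  dplyr::arrange(res, .data$start, .data$motif_len)
}

#' Find perfect SSRs in a genome
#'
#' Reports every maximal perfect tandem repeat with motif length 1-6 whose
#' copy number meets the per-length threshold, exactly once, at the
#' smallest motif length at which it qualifies (only primitive motifs are
#' emitted, so a poly-A run is mono, never "AA"). Tracts never extend
#' across `N`. Output is sorted by chromosome and start.
#'
#' @param genome Genome tibble from [read_genome_fasta()] (columns
#'   `chrom_id`, `sequence`), or any tibble with those columns.
#' @param params [ssr_params()].
#' @return Tibble of perfect SSR loci: `chrom_id`, `start`, `end` (1-based
#'   inclusive), `motif`, `motif_len`, `n_repeats`, `kind = "perfect"`.
#' @export
find_perfect_ssrs <- function(genome, params = ssr_params()) {
  assert_cols(genome, c("chrom_id", "sequence"))
  res <- purrr::map2(genome$chrom_id, genome$sequence, function(id, seq) {
    hits <- scan_perfect_ssrs(seq, params)
    if (nrow(hits)) hits$chrom_id <- id
    hits
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0L) {
    return(tibble(chrom_id = character(), start = integer(), end = integer(),
                  motif = character(), motif_len = integer(),
                  n_repeats = integer(), kind = character()))
  }
  res$kind <- "perfect"
  dplyr::select(res, "chrom_id", "start", "end", "motif", "motif_len",
                "n_repeats", "kind")
}

#' Merge nearby perfect SSRs into compound loci
#'
#' Maximal chains of perfect tracts on one chromosome whose successive gaps
#' are strictly less than `compound_max_gap` bp become a single compound
#' locus; isolated tracts pass through unchanged. The member tracts of a
#' compound are kept in the `members` list column, so total bp covered by
#' perfect tracts is conserved.
#'
#' @param ssrs Output of [find_perfect_ssrs()], sorted by start within each
#'   chromosome (unsorted input is an error).
#' @param params [ssr_params()].
#' @return Tibble like `ssrs` plus a `members` list column (NULL for
#'   perfect loci, member tibble for compounds); compound rows have
#'   `motif = NA` and span first start to last end.
#' @export
merge_compound <- function(ssrs, params = ssr_params()) {
  assert_cols(ssrs, c("chrom_id", "start", "end", "motif", "motif_len",
                      "n_repeats"))
  if (nrow(ssrs) == 0L) {
    ssrs$members <- list()
    return(ssrs)
  }
  pieces <- lapply(split(ssrs, ssrs$chrom_id), function(x) {
    if (is.unsorted(x$start)) {
      abort(sprintf("SSRs on chromosome '%s' are not sorted by start",
                    x$chrom_id[1]))
    }
    gap <- x$start[-1] - x$end[-nrow(x)] - 1L
    chain <- cumsum(c(0L, as.integer(!(gap < params$compound_max_gap)))) + 1L
    dplyr::bind_rows(lapply(split(x, chain), function(ch) {
      if (nrow(ch) == 1L) {
        ch$members <- list(NULL)
        return(ch)
      }
      tibble(
        chrom_id = ch$chrom_id[1],
        start = min(ch$start),
        end = max(ch$end),
        motif = NA_character_,
        motif_len = NA_integer_,
        n_repeats = NA_integer_,
        kind = "compound",
        members = list(dplyr::select(ch, -dplyr::any_of("members")))
      )
    }))
  })
  res <- dplyr::bind_rows(pieces)
  dplyr::arrange(res, .data$chrom_id, .data$start)
}

# Distance (bp) from an SSR tract to an anchor position; 0 when the anchor
# falls inside the tract.
tract_anchor_distance <- function(start, end, anchor) {
  pmax(0L, start - anchor, anchor - end)
}

#' Co-localize InDels with SSRs in their flanks
#'
#' For each InDel, the SSR search runs on the window `anchor +/-
#' flank_size` (anchor = VCF POS), clipped to the chromosome; compound
#' merging is applied within the window. An InDel with at least one
#' qualifying SSR tract overlapping the window yields exactly one
#' InDel-SSR locus; its repeat class comes from the member SSR nearest the
#' anchor (`compound` when that member is a compound locus).
#'
#' @param indels Tibble from [read_indel_vcf()].
#' @param genome Genome tibble.
#' @param params [ssr_params()].
#' @return Tibble of InDel-SSR loci: `marker_id`, `chrom_id`, `anchor_pos`,
#'   `ref_allele`, `alt_alleles`, `repeat_class`, `motif`, `ssrs` (list
#'   column of the window's SSR loci in genomic coordinates), `genotypes`
#'   (carried through when present).
#' @export
call_indel_ssrs <- function(indels, genome, params = ssr_params()) {
  assert_cols(indels, c("chrom_id", "pos", "ref_allele", "alt_alleles"))
  flank <- params$flank_size
  rows <- lapply(seq_len(nrow(indels)), function(i) {
    chrom <- indels$chrom_id[i]
    pos <- indels$pos[i]
    clen <- chrom_length(genome, chrom)
    if (pos < 1L || pos > clen) {
      abort(sprintf("InDel %s:%d lies outside chromosome bounds (length %d)",
                    chrom, pos, clen))
    }
    w_start <- max(1L, pos - flank)
    w_end <- min(clen, pos + flank)
    win <- substr(chrom_sequence(genome, chrom), w_start, w_end)
    hits <- scan_perfect_ssrs(win, params)
    if (nrow(hits) == 0L) return(NULL)
    hits$start <- hits$start + w_start - 1L
    hits$end <- hits$end + w_start - 1L
    hits$chrom_id <- chrom
    hits$kind <- "perfect"
    merged <- merge_compound(hits, params)
    dist <- tract_anchor_distance(merged$start, merged$end, pos)
    nearest <- which.min(dist)
    cls <- if (merged$kind[nearest] == "compound") "compound" else
      repeat_class_of(merged$motif_len[nearest])
    tibble(
      marker_id = sprintf("%s_%d", chrom, pos),
      chrom_id = chrom,
      anchor_pos = pos,
      ref_allele = indels$ref_allele[i],
      alt_alleles = list(indels$alt_alleles[[i]]),
      repeat_class = cls,
      motif = merged$motif[nearest],
      ssrs = list(merged),
      genotypes = list(if ("genotypes" %in% names(indels))
        indels$genotypes[[i]] else NULL)
    )
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    return(tibble(marker_id = character(), chrom_id = character(),
                  anchor_pos = integer(), ref_allele = character(),
                  alt_alleles = list(), repeat_class = character(),
                  motif = character(), ssrs = list(), genotypes = list()))
  }
  res
}

#' Repeat-type composition of InDel-SSR loci
#'
#' Per-class counts and percentages (summing to 100 up to rounding), and a
#' per-motif table in which a motif is pooled with its reverse complement
#' but not with its rotations (AG/CT and GA/TC are distinct classes).
#' Compound loci form their own class and do not enter the motif table.
#'
#' @param loci Output of [call_indel_ssrs()].
#' @return List of class `repeat_composition` with tibbles `by_class`
#'   (`repeat_class`, `n`, `pct`) and `by_motif` (`motif_class`, `n`,
#'   `pct`).
#' @export
classify_repeat_types <- function(loci) {
  if (nrow(loci) == 0L) abort("no loci to classify")
  lv <- c(REPEAT_CLASS_NAMES, "compound")
  by_class <- loci |>
    dplyr::count(repeat_class = factor(.data$repeat_class, levels = lv),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
  simple <- loci[loci$repeat_class != "compound", , drop = FALSE]
  by_motif <- if (nrow(simple)) {
    simple |>
      dplyr::mutate(motif_class = motif_class_label(.data$motif)) |>
      dplyr::count(.data$motif_class, name = "n") |>
      dplyr::mutate(pct = 100 * .data$n / nrow(loci)) |>
      dplyr::arrange(dplyr::desc(.data$n))
  } else {
    tibble(motif_class = character(), n = integer(), pct = numeric())
  }
  structure(list(by_class = by_class, by_motif = by_motif),
            class = "repeat_composition")
}

#' Per-chromosome distribution report for InDel-SSR loci
#'
#' Density is loci per Mb of chromosome (2 decimals); the InDel-SSR/InDel
#' ratio is a percentage (2 decimals). The genome summary reports totals,
#' the per-chromosome mean count, and the *unweighted* mean of
#' per-chromosome densities.
#'
#' @param loci InDel-SSR loci (tibble with `chrom_id`), or `NULL` when
#'   using `counts`.
#' @param indels InDel tibble (with `chrom_id`), or `NULL`.
#' @param genome Genome tibble (chrom lengths), or `NULL`.
#' @param counts Alternatively, a precomputed count table with columns
#'   `chrom_id`, `chrom_len`, `n_indels`, `n_indel_ssrs`.
#' @return Tibble of class `chrom_report` with per-chromosome rows and a
#'   `summary` attribute (see [glance.chrom_report()]).
#' @export
chromosome_report <- function(loci = NULL, indels = NULL, genome = NULL,
                              counts = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(loci), !is.null(indels), !is.null(genome))
    counts <- tibble(
      chrom_id = genome$chrom_id,
      chrom_len = genome$length,
      n_indels = as.integer(table(factor(indels$chrom_id,
                                         levels = genome$chrom_id))),
      n_indel_ssrs = as.integer(table(factor(loci$chrom_id,
                                             levels = genome$chrom_id)))
    )
  }
  assert_cols(counts, c("chrom_id", "chrom_len", "n_indels", "n_indel_ssrs"))
  if (any(counts$chrom_len <= 0)) abort("zero-length chromosome in report")
  rep <- counts |>
    dplyr::mutate(
      density_per_mb = round(.data$n_indel_ssrs / (.data$chrom_len / 1e6), 2),
      ratio_pct = round(ifelse(.data$n_indels > 0,
                               100 * .data$n_indel_ssrs / .data$n_indels, 0), 2)
    )
  summary <- tibble(
    total_len = sum(rep$chrom_len),
    total_indels = sum(rep$n_indels),
    total_indel_ssrs = sum(rep$n_indel_ssrs),
    mean_count = mean(rep$n_indel_ssrs),
    mean_density_per_mb = round(mean(rep$density_per_mb), 2),
    overall_ratio_pct = round(ifelse(sum(rep$n_indels) > 0,
      100 * sum(rep$n_indel_ssrs) / sum(rep$n_indels), 0), 2)
  )
  structure(rep, summary = summary,
            class = c("chrom_report", class(rep)))
}

#' @rdname chromosome_report
#' @param x A `chrom_report`.
#' @param ... Unused.
#' @export
glance.chrom_report <- function(x, ...) {
  attr(x, "summary")
}
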