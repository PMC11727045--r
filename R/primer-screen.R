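# Primer candidate enumeration under marker-development constraints,
# product-level screening, and in-silico PCR banding.

#' Primer design constraints
#'
#' Defaults match common InDel-SSR marker development practice: primer
#' length 16-24 nt, product 100-300 bp, Tm 50-60 degrees C optimized at 55,
#' at most 3 degrees Tm difference within a pair.
#'
#' @param primer_len Integer range of primer lengths (nt).
#' @param product_range Product length range (bp) on the reference.
#' @param tm_range Allowed Tm window (degrees C).
#' @param tm_opt Tm optimum used for ranking.
#' @param max_tm_diff Maximum |Tm(fwd) - Tm(rev)|.
#' @param top_k Number of ranked pairs returned per locus.
#' @param max_side_candidates Per-side cap (kept by Tm closeness to
#'   `tm_opt`) bounding the pairing enumeration.
#' @return A `primer_constraints` list.
#' @export
primer_constraints <- function(primer_len = 16:24,
                               product_range = c(100L, 300L),
                               tm_range = c(50, 60),
                               tm_opt = 55,
                               max_tm_diff = 3,
                               top_k = 3L,
                               max_side_candidates = 400L) {
  structure(list(primer_len = as.integer(primer_len),
                 product_range = as.integer(product_range),
                 tm_range = tm_range, tm_opt = tm_opt,
                 max_tm_diff = max_tm_diff, top_k = as.integer(top_k),
                 max_side_candidates = as.integer(max_side_candidates)),
            class = "primer_constraints")
}

#' Oligo melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` for oligos shorter than 14 nt, otherwise
#' the GC-count formula `64.9 + 41 * (n_GC - 16.4) / L` where `L` is the
#' oligo length. Deterministic and monotone
#' nondecreasing in GC count at fixed length. Sequences containing
#' non-ACGT characters get `NA` (candidates with N are rejected upstream).
#'
#' @param seq Character vector of primer sequences.
#' @return Numeric vector of Tm values in degrees C.
#' @export
melting_temperature <- function(seq) {
  stopifnot(is.character(seq), all(nchar(seq) > 0L))
  L <- nchar(seq)
  n_gc <- nchar(gsub("[^GC]", "", seq))
  n_at <- nchar(gsub("[^AT]", "", seq))
  tm <- ifelse(L < 14L,
               2 * n_at + 4 * n_gc,
               64.9 + 41 * (n_gc - 16.4) / L)
  tm[n_gc + n_at != L] <- NA_real_
  tm
}

# Enumerate primer candidates anchored on one strand within [lo, hi]
# (candidate start positions for forward, end positions for reverse).
enumerate_side <- function(seq, positions, lens, forward, constraints) {
  grid <- tidyr::expand_grid(pos = positions, len = lens)
  if (forward) {
    grid$start <- grid$pos
    grid$end <- grid$pos + grid$len - 1L
  } else {
    grid$end <- grid$pos
    grid$start <- grid$pos - grid$len + 1L
  }
  grid <- grid[grid$start >= 1L & grid$end <= nchar(seq), , drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  grid$site <- substr(rep(seq, nrow(grid)), grid$start, grid$end)
  grid$tm <- melting_temperature(grid$site)
  grid <- grid[!is.na(grid$tm) &
                 grid$tm >= constraints$tm_range[1] &
                 grid$tm <= constraints$tm_range[2], , drop = FALSE]
  grid
}

#' Enumerate and rank primer pairs for an InDel-SSR locus
#'
#' Exhaustively enumerates primer pairs within the locus flanks whose
#' product (on the reference) spans the InDel anchor and satisfies all
#' [primer_constraints()], then ranks them by `|Tm - tm_opt|` summed over
#' the pair, then by `|product - 200|`, then by leftmost forward start and
#' leftmost reverse end, returning the top `top_k`.
#'
#' @param locus One row of [call_indel_ssrs()] output.
#' @param genome Genome tibble.
#' @param constraints [primer_constraints()].
#' @return Tibble of primer pairs: `marker_id`, `fwd_seq`, `rev_seq`,
#'   `fwd_start`, `rev_end` (1-based genomic), `tm_fwd`, `tm_rev`,
#'   `product_len_ref`. Empty when no feasible pair exists.
#' @export
design_candidates <- function(locus, genome, constraints = primer_constraints()) {
  stopifnot(nrow(locus) == 1L)
  chrom <- locus$chrom_id
  seq <- chrom_sequence(genome, chrom)
  anchor <- locus$anchor_pos
  max_prod <- constraints$product_range[2]
  empty <- tibble(marker_id = character(), fwd_seq = character(),
                  rev_seq = character(), fwd_start = integer(),
                  rev_end = integer(), tm_fwd = numeric(),
                  tm_rev = numeric(), product_len_ref = integer())

  fwd_pos <- seq.int(max(1L, anchor - max_prod + 1L), anchor)
  rev_pos <- seq.int(anchor, min(nchar(seq), anchor + max_prod - 1L))
  fwd <- enumerate_side(seq, fwd_pos, constraints$primer_len, TRUE, constraints)
  rev <- enumerate_side(seq, rev_pos, constraints$primer_len, FALSE, constraints)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)

  cap <- constraints$max_side_candidates
  fwd <- fwd[order(abs(fwd$tm - constraints$tm_opt), fwd$start, fwd$len), ]
  rev <- rev[order(abs(rev$tm - constraints$tm_opt), rev$end, rev$len), ]
  fwd <- head(fwd, cap)
  rev <- head(rev, cap)

  pairs <- tidyr::expand_grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  prod_len <- rev$end[pairs$r] - fwd$start[pairs$f] + 1L
  ok <- prod_len >= constraints$product_range[1] &
    prod_len <= constraints$product_range[2] &
    fwd$end[pairs$f] < rev$start[pairs$r] &              # non-overlapping
    fwd$start[pairs$f] <= anchor & rev$end[pairs$r] >= anchor &
    abs(fwd$tm[pairs$f] - rev$tm[pairs$r]) <= constraints$max_tm_diff
  if (!any(ok)) return(empty)
  pairs <- pairs[ok, , drop = FALSE]
  prod_len <- prod_len[ok]

  score_tm <- abs(fwd$tm[pairs$f] - constraints$tm_opt) +
    abs(rev$tm[pairs$r] - constraints$tm_opt)
  ord <- order(score_tm, abs(prod_len - 200L),
               fwd$start[pairs$f], rev$end[pairs$r])
  take <- head(ord, constraints$top_k)
  tibble(
    marker_id = locus$marker_id,
    fwd_seq = fwd$site[pairs$f[take]],
    rev_seq = revcomp(substr(rep(seq, length(take)),
                             rev$start[pairs$r[take]],
                             rev$end[pairs$r[take]])),
    fwd_start = fwd$start[pairs$f[take]],
    rev_end = rev$end[pairs$r[take]],
    tm_fwd = fwd$tm[pairs$f[take]],
    tm_rev = rev$tm[pairs$r[take]],
    product_len_ref = prod_len[take]
  )
}

#' Screening criteria for InDel-SSR markers
#'
#' A marker passes when its predicted product contains at least
#' `min_repeat_span` bp of SSR tract, those tract bases are at least
#' `min_at_fraction` A/T, and the product contains the InDel anchor.
#'
#' @param min_repeat_span Minimum total SSR tract bp inside the product.
#' @param min_at_fraction Minimum A/T fraction of in-product tract bases.
#' @param require_indel_in_product Whether the anchor must be inside the
#'   product.
#' @return A `screen_criteria` list.
#' @export
screen_criteria <- function(min_repeat_span = 18L,
                            min_at_fraction = 0.5,
                            require_indel_in_product = TRUE) {
  stopifnot(min_repeat_span >= 0,
            min_at_fraction >= 0, min_at_fraction <= 1)
  structure(list(min_repeat_span = as.integer(min_repeat_span),
                 min_at_fraction = min_at_fraction,
                 require_indel_in_product = require_indel_in_product),
            class = "screen_criteria")
}

# Perfect member tracts of a locus (compounds expanded to their members).
locus_member_tracts <- function(locus) {
  ssrs <- locus$ssrs[[1]]
  parts <- lapply(seq_len(nrow(ssrs)), function(i) {
    if (ssrs$kind[i] == "compound") ssrs$members[[i]] else
      ssrs[i, c("chrom_id", "start", "end", "motif", "motif_len", "n_repeats")]
  })
  dplyr::bind_rows(parts)
}

#' Screen primer pairs against marker criteria
#'
#' @param pairs Primer pairs from [design_candidates()].
#' @param loci InDel-SSR loci (matched to `pairs` by `marker_id`).
#' @param genome Genome tibble.
#' @param criteria [screen_criteria()].
#' @return `pairs` with logical `pass`, numeric `repeat_span_bp` and
#'   `at_fraction`, and a `reasons` character column listing every violated
#'   criterion (empty string when passing).
#' @export
screen_markers <- function(pairs, loci, genome,
                           criteria = screen_criteria()) {
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, pass = logical(0),
                         repeat_span_bp = integer(0),
                         at_fraction = numeric(0), reasons = character(0)))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    locus <- loci[loci$marker_id == pair$marker_id, ]
    if (nrow(locus) != 1L) {
      abort(sprintf("marker '%s' not found (or duplicated) in loci",
                    pair$marker_id))
    }
    tracts <- locus_member_tracts(locus)
    p_start <- pair$fwd_start
    p_end <- pair$rev_end
    ov_start <- pmax(tracts$start, p_start)
    ov_end <- pmin(tracts$end, p_end)
    keep <- ov_end >= ov_start
    span <- sum(ov_end[keep] - ov_start[keep] + 1L)
    at_frac <- if (span > 0L) {
      seq <- chrom_sequence(genome, locus$chrom_id)
      bases <- unlist(mapply(function(s, e)
        strsplit(substr(seq, s, e), "", fixed = TRUE)[[1]],
        ov_start[keep], ov_end[keep], SIMPLIFY = FALSE))
      mean(bases %in% c("A", "T"))
    } else 0
    anchor_in <- locus$anchor_pos >= p_start && locus$anchor_pos <= p_end
    reasons <- c(
      if (span < criteria$min_repeat_span)
        sprintf("repeat span %d < %d bp", span, criteria$min_repeat_span),
      if (at_frac < criteria$min_at_fraction)
        sprintf("AT fraction %.2f < %.2f", at_frac, criteria$min_at_fraction),
      if (criteria$require_indel_in_product && !anchor_in)
        "InDel anchor outside product"
    )
    tibble(pass = length(reasons) == 0L, repeat_span_bp = span,
           at_fraction = at_frac,
           reasons = paste(reasons, collapse = "; "))
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res))
}

#' Predict electrophoretic bands by in-silico PCR
#'
#' Each individual's band set at a marker is the set of distinct product
#' lengths implied by its two allele copies: the reference product length
#' shifted by each allele's InDel length difference. Homozygotes show one
#' band, heterozygotes two; missing genotypes give NA for all of the
#' marker's bands.
#'
#' @param pairs Screened primer pairs (one row per marker used).
#' @param loci InDel-SSR loci carrying per-sample `genotypes` matrices.
#' @return A `band_matrix` tibble whose rows are the union of observed
#'   band lengths per marker (`band_id` = `<marker>_<length>`).
#' @export
in_silico_pcr <- function(pairs, loci) {
  stopifnot(nrow(pairs) > 0L)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    locus <- loci[loci$marker_id == pair$marker_id, ]
    stopifnot(nrow(locus) == 1L)
    gt <- locus$genotypes[[1]]
    if (is.null(gt)) {
      abort(sprintf("marker '%s' has no per-sample genotypes", pair$marker_id))
    }
    ref_len <- nchar(locus$ref_allele)
    offsets <- c(0L, nchar(locus$alt_alleles[[1]]) - ref_len)
    allele_band <- pair$product_len_ref + offsets  # index 1 = ref allele 0
    inds <- rownames(gt)
    band_sets <- lapply(seq_len(nrow(gt)), function(r) {
      a <- gt[r, ]
      if (anyNA(a)) return(NA_integer_)
      unique(allele_band[a + 1L])
    })
    lens <- sort(unique(unlist(band_sets[!is.na(band_sets)])))
    if (length(lens) == 0L) return(NULL)
    m <- matrix(NA_integer_, nrow = length(lens), ncol = length(inds),
                dimnames = list(NULL, inds))
    for (r in seq_along(band_sets)) {
      if (length(band_sets[[r]]) == 1L && is.na(band_sets[[r]][1])) next
      m[, r] <- as.integer(lens %in% band_sets[[r]])
    }
    dplyr::bind_cols(
      tibble(marker_id = pair$marker_id,
             band_id = sprintf("%s_%d", pair$marker_id, lens)),
      as_tibble(m)
    )
  })
  res <- dplyr::bind_rows(out)
  validate_band_matrix(res)
}
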