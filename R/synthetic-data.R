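# Synthetic genomes, cohorts, band matrices and phenotypes with known
# ground truth, for validating every stage of the pipeline.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: a
#' 121-individual cohort drawn from 3 admixed subpopulations, genotyped at
#' 219 multi-allelic markers, phenotyped for 10 traits in 2 years, with a
#' planted-QTL plus polygenic trait model.
#'
#' @param seed Base seed; every downstream draw derives from it.
#' @param n_chromosomes,chrom_len Genome shape (chromosomes x bp).
#' @param n_planted_ssrs Named vector: planted SSR tracts per motif length
#'   `"1"`..`"6"`; copy numbers straddle the detection thresholds.
#' @param n_indels Number of planted InDels.
#' @param frac_indels_near_ssr Fraction of InDels placed within 500 bp of
#'   an above-threshold planted SSR.
#' @param n_genes Planted gene annotations (for candidate windows).
#' @param n_individuals,n_subpops Cohort shape.
#' @param admixture_alpha Symmetric Dirichlet parameter for individual
#'   admixture proportions (small = near-pure assignment).
#' @param subpop_divergence Concentration divisor for subpopulation allele
#'   frequencies around the base frequencies (larger = more divergence).
#' @param inbreeding Probability that an individual's two allele draws are
#'   copies (creates the expected Ho < He deficit).
#' @param n_markers Number of markers in the cohort.
#' @param n_alleles_range Range of allele counts per marker.
#' @param n_traits,n_years Phenotype shape.
#' @param planted_qtl Tibble (`marker`, `trait`, `effect`) of marker
#'   effects in phenotype-sd units on the standardized dosage; `NULL`
#'   plants two QTLs by default.
#' @param h2_polygenic Polygenic heritability of every trait.
#' @param trait_noise_sd Environmental noise sd per year; `NULL` derives
#'   it so total trait variance is ~1 (error if that leaves no variance).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_len = 200000L,
                       n_planted_ssrs = c(`1` = 6L, `2` = 6L, `3` = 6L,
                                          `4` = 4L, `5` = 4L, `6` = 4L),
                       n_indels = 60L,
                       frac_indels_near_ssr = 0.6,
                       n_genes = 30L,
                       n_individuals = 121L,
                       n_subpops = 3L,
                       admixture_alpha = 0.2,
                       subpop_divergence = 0.3,
                       inbreeding = 0.1,
                       n_markers = 219L,
                       n_alleles_range = c(2L, 6L),
                       n_traits = 10L,
                       n_years = 2L,
                       planted_qtl = NULL,
                       h2_polygenic = 0.3,
                       trait_noise_sd = NULL) {
  if (is.null(planted_qtl)) {
    planted_qtl <- tibble(marker = c("m001", "m002"),
                          trait = c("trait01", "trait02"),
                          effect = c(0.6, 0.6))
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chrom_len = chrom_len, n_planted_ssrs = n_planted_ssrs,
              n_indels = n_indels,
              frac_indels_near_ssr = frac_indels_near_ssr,
              n_genes = n_genes, n_individuals = n_individuals,
              n_subpops = n_subpops, admixture_alpha = admixture_alpha,
              subpop_divergence = subpop_divergence,
              inbreeding = inbreeding, n_markers = n_markers,
              n_alleles_range = n_alleles_range, n_traits = n_traits,
              n_years = n_years, planted_qtl = planted_qtl,
              h2_polygenic = h2_polygenic, trait_noise_sd = trait_noise_sd)
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_len >= 2000,
            all(cfg$n_planted_ssrs >= 0), cfg$n_indels >= 0,
            cfg$frac_indels_near_ssr >= 0, cfg$frac_indels_near_ssr <= 1,
            cfg$n_individuals >= 2, cfg$n_subpops >= 1,
            cfg$h2_polygenic >= 0, cfg$h2_polygenic <= 1,
            cfg$inbreeding >= 0, cfg$inbreeding < 1)
  structure(cfg, class = "sim_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

random_primitive_motif <- function(len) {
  # AT-biased base composition, as in the AT-rich repeat classes that
  # dominate plant genomes
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)),
               collapse = "")
    if (is_primitive_motif(m) &&
        (len == 1L || substr(m, 1, 1) != substr(m, len, len))) {
      return(m)
    }
  }
}

# Break any unplanted repeat at or just below threshold so that
# recall/precision against the truth table is exact: every tract the
# finder may report is a planted one.
sanitize_background <- function(seq, params) {
  strict <- ssr_params(min_repeats = pmax(params$min_repeats - 1L, 2L),
                       compound_max_gap = params$compound_max_gap,
                       flank_size = params$flank_size)
  for (iter in 1:100) {
    hits <- scan_perfect_ssrs(seq, strict)
    if (nrow(hits) == 0L) return(seq)
    for (i in seq_len(nrow(hits))) {
      mid <- (hits$start[i] + hits$end[i]) %/% 2L
      cur <- substr(seq, mid, mid)
      repl <- setdiff(c("A", "C", "G", "T"), cur)[sample.int(3, 1)]
      substr(seq, mid, mid) <- repl
    }
  }
  abort("could not sanitize background sequence of accidental repeats")
}

# After planting, scrub any reportable tract that is not a planted
# above-threshold one (single-base edits near plant boundaries can create
# them); planted spans are never touched.
repair_unplanned_ssrs <- function(seq, chrom, truth, params) {
  planted <- truth[truth$chrom_id == chrom & truth$above_threshold, ,
                   drop = FALSE]
  for (iter in 1:20) {
    hits <- scan_perfect_ssrs(seq, params)
    ok <- rep(FALSE, nrow(hits))
    if (nrow(hits) && nrow(planted)) {
      key_h <- paste(hits$start, hits$motif, hits$n_repeats)
      key_p <- paste(planted$start, planted$motif, planted$n_repeats)
      ok <- key_h %in% key_p
    }
    if (all(ok)) return(seq)
    bad <- hits[!ok, , drop = FALSE]
    for (i in seq_len(nrow(bad))) {
      if (nrow(planted) && any(bad$end[i] >= planted$start &
            bad$start[i] <= planted$start +
              planted$motif_len * planted$n_repeats - 1L)) {
        abort("planted SSR corrupted during genome simulation")
      }
      mid <- (bad$start[i] + bad$end[i]) %/% 2L
      cur <- substr(seq, mid, mid)
      substr(seq, mid, mid) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
  }
  abort("could not repair unplanned repeats after planting")
}

#' Simulate a genome with planted SSRs and InDels
#'
#' Background sequence is i.i.d. uniform ACGT, then scrubbed of accidental
#' near-threshold repeats so the truth tables are exhaustive. Planted SSR
#' tracts use random primitive motifs with copy numbers below, at and
#' above the detection thresholds; a configured fraction of InDels is
#' placed within 500 bp of an above-threshold SSR, the rest far from any.
#' Gene annotations are planted uniformly for candidate-window tests.
#'
#' @param config A [sim_config()].
#' @param params [ssr_params()] defining the thresholds being straddled.
#' @return List: `genome` (tibble), `ssr_truth` (`chrom_id`, `start`,
#'   `motif`, `motif_len`, `n_repeats`, `above_threshold`), `indel_truth`
#'   (`chrom_id`, `pos`, `ref_allele`, `alt_alleles`, `near_ssr`),
#'   `genes` (tibble).
#' @export
simulate_genome <- function(config = sim_config(), params = ssr_params()) {
  set.seed(derive_seed(config$seed, 1L))
  n_chr <- config$n_chromosomes
  chrom_ids <- sprintf("chr%d", seq_len(n_chr))
  seqs <- vapply(chrom_ids, function(id) {
    sanitize_background(paste(sample(c("A", "C", "G", "T"),
                                     config$chrom_len, replace = TRUE),
                              collapse = ""), params)
  }, character(1))

  # plant SSRs on an evenly spaced grid, jittered, one feature per slot
  plant <- list(); slot_used <- list()
  total_ssrs <- sum(config$n_planted_ssrs)
  n_feat <- total_ssrs + config$n_indels
  per_chr <- as.integer(ceiling(n_feat / n_chr))
  spacing <- as.integer(config$chrom_len - 2000L) %/% (per_chr + 1L)
  if (spacing < 1200L) {
    abort("overcrowded config: planted features would overlap (increase chrom_len)")
  }
  slots <- tibble(
    chrom_id = rep(chrom_ids, each = per_chr),
    pos = rep(1000L + spacing * seq_len(per_chr), times = n_chr)
  )
  slots$pos <- as.integer(slots$pos)
  slots <- slots[sample.int(nrow(slots)), ]

  ssr_truth <- list()
  si <- 0L
  for (L in 1:6) {
    nL <- config$n_planted_ssrs[[as.character(L)]]
    if (nL == 0L) next
    thr <- params$min_repeats[[as.character(L)]]
    # straddle the threshold: below, at, and well above (long enough to
    # clear the 18 bp screening span for di+ motifs)
    counts <- rep(c(thr - 1L, thr, thr + 5L), length.out = nL)
    for (v in seq_len(nL)) {
      si <- si + 1L
      slot <- slots[si, ]
      motif <- random_primitive_motif(L)
      tract <- strrep(motif, counts[v])
      chrom_i <- match(slot$chrom_id, chrom_ids)
      s <- seqs[chrom_i]
      substr(s, slot$pos, slot$pos + nchar(tract) - 1L) <- tract
      # hard boundaries so the planted phase and count are exact: the base
      # before the tract must differ from the motif's last character, the
      # base after it from the motif's first
      left <- slot$pos - 1L
      right <- slot$pos + nchar(tract)
      if (left >= 1L && substr(s, left, left) == substr(motif, L, L)) {
        substr(s, left, left) <-
          setdiff(c("A", "C", "G", "T"), substr(motif, L, L))[1]
      }
      if (right <= nchar(s) &&
          substr(s, right, right) == substr(motif, 1L, 1L)) {
        substr(s, right, right) <-
          setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L))[1]
      }
      seqs[chrom_i] <- s
      ssr_truth[[si]] <- tibble(chrom_id = slot$chrom_id, start = slot$pos,
                                motif = motif, motif_len = L,
                                n_repeats = counts[v],
                                above_threshold = counts[v] >= thr)
    }
  }
  ssr_truth <- dplyr::bind_rows(ssr_truth)
  for (ci in seq_len(n_chr)) {
    seqs[ci] <- repair_unplanned_ssrs(seqs[ci], chrom_ids[ci], ssr_truth,
                                      params)
  }

  # plant InDels: near an above-threshold SSR or far from all SSRs
  n_near <- round(config$n_indels * config$frac_indels_near_ssr)
  above <- ssr_truth[ssr_truth$above_threshold, , drop = FALSE]
  if (n_near > 0L && nrow(above) == 0L) {
    abort("frac_indels_near_ssr > 0 requires above-threshold planted SSRs")
  }
  indel_truth <- list()
  used_pos <- character(0)
  for (v in seq_len(config$n_indels)) {
    near <- v <= n_near
    if (near) {
      host <- above[((v - 1L) %% nrow(above)) + 1L, ]
      repeat {
        # adjacent to or inside the repeat tract, as for real InDel-SSRs
        pos <- host$start + sample(c(-80:-15, 15:150), 1L)
        if (pos >= 15L && !paste(host$chrom_id, pos) %in% used_pos) break
      }
      chrom <- host$chrom_id
    } else {
      si <- si + 1L
      slot <- slots[si, ]
      pos <- slot$pos
      chrom <- slot$chrom_id
    }
    chrom_i <- match(chrom, chrom_ids)
    s <- seqs[chrom_i]
    if (runif(1) < 0.5) {  # deletion of 2-8 bp
      dl <- sample(2:8, 1L)
      ref <- substr(s, pos, pos + dl)
      alt <- substr(s, pos, pos)
    } else {               # insertion of 2-8 bp
      ref <- substr(s, pos, pos)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(2:8, 1L),
                          replace = TRUE), collapse = "")
      alt <- paste0(ref, ins)
    }
    used_pos <- c(used_pos, paste(chrom, pos))
    indel_truth[[v]] <- tibble(chrom_id = chrom, pos = pos,
                               ref_allele = ref, alt_alleles = list(alt),
                               near_ssr = near)
  }
  indel_truth <- dplyr::bind_rows(indel_truth)
  indel_truth <- dplyr::arrange(indel_truth, .data$chrom_id, .data$pos)

  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom_id = sample(chrom_ids, config$n_genes, replace = TRUE),
    start = sample.int(config$chrom_len - 3000L, config$n_genes)
  )
  genes$end <- genes$start + sample(500:2500, config$n_genes,
                                    replace = TRUE)
  genes$strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- dplyr::arrange(genes, .data$chrom_id, .data$start)

  list(
    genome = tibble(chrom_id = chrom_ids, sequence = unname(seqs),
                    length = nchar(seqs)),
    ssr_truth = ssr_truth,
    indel_truth = indel_truth,
    genes = genes
  )
}

#' Simulate a structured, admixed cohort
#'
#' Per marker, subpopulation allele frequencies are Dirichlet draws around
#' shared base frequencies; individual admixture proportions come from a
#' symmetric Dirichlet; each individual's genotype is two allele draws
#' from its admixture-weighted frequencies (with probability `inbreeding`
#' the second draw copies the first). Band matrices follow the codominant
#' band model (one band per allele).
#'
#' @param config A [sim_config()].
#' @param loci Optional InDel-SSR loci (from [call_indel_ssrs()] on a
#'   simulated genome); markers are then attached to the first
#'   `n_markers` loci (recycling alleles onto the locus' alt set).
#' @return List: `bands` (band matrix), `genotypes` (long tibble), `q_truth`
#'   (tibble), `kinship_truth` (realized allele-sharing matrix),
#'   `subpop_freqs`, `individual_ids`.
#' @export
simulate_cohort <- function(config = sim_config(), loci = NULL) {
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_individuals
  s <- config$n_subpops
  inds <- sprintf("ind%03d", seq_len(n))
  if (is.null(loci)) {
    m <- config$n_markers
    markers <- sprintf("m%03d", seq_len(m))
    n_alleles <- sample(config$n_alleles_range[1]:config$n_alleles_range[2],
                        m, replace = TRUE)
  } else {
    # markers ride on InDel-SSR loci: alleles are ref + alts
    m <- min(config$n_markers, nrow(loci))
    loci <- loci[seq_len(m), , drop = FALSE]
    markers <- loci$marker_id
    n_alleles <- 1L + lengths(loci$alt_alleles)
  }

  q <- rdirichlet(n, rep(config$admixture_alpha, s))
  subpop_freqs <- lapply(seq_len(m), function(j) {
    base <- as.numeric(rdirichlet(1, rep(1, n_alleles[j])))
    conc <- pmax(base, 1e-3) / config$subpop_divergence
    rdirichlet(s, conc)    # s x n_alleles
  })

  a1 <- matrix(NA_integer_, n, m)
  a2 <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    pf <- q %*% subpop_freqs[[j]]   # n x n_alleles individual frequencies
    for (i in seq_len(n)) {
      draw <- sample.int(n_alleles[j], 2L, replace = TRUE, prob = pf[i, ])
      if (runif(1) < config$inbreeding) draw[2] <- draw[1]
      a1[i, j] <- min(draw); a2[i, j] <- max(draw)
    }
  }

  genotypes <- tibble(
    marker_id = rep(markers, each = n),
    individual_id = rep(inds, times = m),
    allele1 = as.integer(a1), allele2 = as.integer(a2)
  )

  # codominant band model: allele k of marker j -> band length 100 + 10k
  band_rows <- lapply(seq_len(m), function(j) {
    lens <- 100L + 10L * seq_len(n_alleles[j])
    present <- vapply(seq_len(n_alleles[j]), function(k) {
      as.integer(a1[, j] == k | a2[, j] == k)
    }, integer(n))
    dplyr::bind_cols(
      tibble(marker_id = markers[j],
             band_id = sprintf("%s_%d", markers[j], lens)),
      as_tibble(matrix(t(present), nrow = n_alleles[j],
                       dimnames = list(NULL, inds)))
    )
  })
  bands <- validate_band_matrix(dplyr::bind_rows(band_rows))

  # realized allele-sharing kinship (truth by construction)
  kt <- matrix(1, n, n, dimnames = list(inds, inds))
  for (i in seq_len(n - 1L)) {
    for (j2 in (i + 1L):n) {
      sh <- shared_allele_fraction(a1[i, ], a2[i, ], a1[j2, ], a2[j2, ])
      kt[i, j2] <- kt[j2, i] <- mean(sh)
    }
  }

  q_truth <- dplyr::bind_cols(tibble(individual_id = inds),
                              as_tibble(matrix(q, n,
                                dimnames = list(NULL,
                                  sprintf("Q%d", seq_len(s))))))

  out <- list(bands = bands, genotypes = genotypes, q_truth = q_truth,
              kinship_truth = kt, subpop_freqs = subpop_freqs,
              individual_ids = inds)

  if (!is.null(loci)) {
    # attach per-sample genotypes (0 = ref allele) to the loci so that
    # in_silico_pcr can band them
    loci$genotypes <- lapply(seq_len(m), function(j) {
      g <- cbind(a1[, j], a2[, j]) - 1L
      rownames(g) <- inds
      g
    })
    out$loci <- loci
  }
  out
}

#' Simulate phenotypes with planted marker effects
#'
#' Trait value = planted QTL effects on standardized band dosage +
#' polygenic term (multivariate normal with covariance `h2 * K`) +
#' independent Gaussian year noise around the shared genetic value.
#'
#' @param config A [sim_config()].
#' @param cohort Output of [simulate_cohort()].
#' @return Long trait tibble (`individual_id`, `trait`, `year`, `value`).
#' @export
simulate_traits <- function(config = sim_config(),
                            cohort = simulate_cohort(config)) {
  set.seed(derive_seed(config$seed, 3L))
  inds <- cohort$individual_ids
  n <- length(inds)
  qtl <- config$planted_qtl
  noise_sd <- config$trait_noise_sd
  if (is.null(noise_sd)) {
    max_qtl <- if (nrow(qtl)) {
      max(stats::aggregate(effect ~ trait, data = qtl,
                           FUN = function(e) sum(e^2))$effect)
    } else 0
    resid <- 1 - config$h2_polygenic - max_qtl
    if (resid <= 0) {
      abort("h2_polygenic and planted effects leave no residual variance")
    }
    noise_sd <- sqrt(resid)
  }

  # polygenic values: chol of (clipped) h2 * K
  K <- cohort$kinship_truth
  e <- eigen(K, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  Khalf <- e$vectors %*% (sqrt(e$values) * t(e$vectors))

  dosage_z <- function(marker) {
    g <- cohort$genotypes[cohort$genotypes$marker_id == marker, ]
    if (nrow(g) == 0L) {
      warn(sprintf("planted QTL marker '%s' not in cohort; effect dropped",
                   marker))
      return(rep(0, n))
    }
    g <- g[match(inds, g$individual_id), ]
    dz <- as.numeric(g$allele1 == 1L) + as.numeric(g$allele2 == 1L)
    if (sd(dz) == 0) return(rep(0, n))
    as.numeric(scale(dz))
  }

  rows <- lapply(sprintf("trait%02d", seq_len(config$n_traits)),
                 function(tr) {
    g_qtl <- rep(0, n)
    planted <- qtl[qtl$trait == tr, , drop = FALSE]
    for (r in seq_len(nrow(planted))) {
      g_qtl <- g_qtl + planted$effect[r] * dosage_z(planted$marker[r])
    }
    g_poly <- sqrt(config$h2_polygenic) * as.numeric(Khalf %*% rnorm(n))
    genetic <- g_qtl + g_poly
    dplyr::bind_rows(lapply(seq_len(config$n_years), function(y) {
      tibble(individual_id = inds, trait = tr, year = 2020L + y,
             value = genetic + rnorm(n, sd = noise_sd))
    }))
  })
  dplyr::bind_rows(rows)
}
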