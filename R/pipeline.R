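# End-to-end orchestration on synthetic inputs: simulate -> discover ->
# screen -> pcr -> stats -> diversity -> assoc -> genes, with atomic
# artifact writes and a reproducible run manifest.

write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Flatten InDel-SSR loci to the one-row-per-member-SSR output table.
loci_table <- function(loci) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    tracts <- locus_member_tracts(loci[i, ])
    tibble(marker_id = loci$marker_id[i], chrom = loci$chrom_id[i],
           anchor_pos = loci$anchor_pos[i],
           repeat_class = loci$repeat_class[i],
           motif = tracts$motif, ssr_start = tracts$start,
           ssr_end = tracts$end, n_repeats = tracts$n_repeats,
           kind = if (nrow(loci$ssrs[[i]]) > 1L ||
                      any(loci$ssrs[[i]]$kind == "compound"))
             loci$repeat_class[i] else "perfect")
  })
  dplyr::bind_rows(rows)
}

#' Run the full synthetic pipeline
#'
#' Simulates a genome and cohort, discovers InDel-SSR loci, designs and
#' screens primers, predicts band matrices by in-silico PCR, computes
#' marker statistics, distances/tree/PCA/kinship, trait summaries and the
#' three association models, then candidate-gene windows for stable
#' markers. All artifacts are written atomically to `outdir` together with
#' a `manifest.json` (package version, config hash, seed, per-stage row
#' counts, file checksums — no timestamps, so identical runs give
#' identical manifests).
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param params [ssr_params()].
#' @param constraints [primer_constraints()].
#' @param criteria [screen_criteria()].
#' @param alpha Significance threshold for the association stage.
#' @param resume Reuse the cached state of a previous run in `outdir`,
#'   skipping completed stages.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         params = ssr_params(),
                         constraints = primer_constraints(top_k = 25L),
                         criteria = screen_criteria(),
                         alpha = 0.05, resume = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cache_path <- file.path(outdir, ".pipeline_cache.rds")
  st <- if (resume && file.exists(cache_path)) readRDS(cache_path) else list()
  counts <- list()

  stage <- function(name, fun) {
    if (is.null(st[[name]])) {
      st[[name]] <<- fun()
      saveRDS(st, cache_path)
    }
    st[[name]]
  }

  sim <- stage("genome", function() simulate_genome(config, params))
  write_atomic(function(p) write_genome_fasta(sim$genome, p),
               file.path(outdir, "ref.fa"))
  write_atomic(function(p) write_gene_gff(sim$genes, p),
               file.path(outdir, "genes.gff3"))

  loci0 <- stage("discover", function()
    call_indel_ssrs(sim$indel_truth, sim$genome, params))
  counts$indel_ssr_loci <- nrow(loci0)

  cohort <- stage("cohort", function()
    simulate_cohort(config, loci = loci0))
  loci <- cohort$loci
  vcf_tbl <- dplyr::transmute(loci, .data$chrom_id, pos = .data$anchor_pos,
                              .data$marker_id, .data$ref_allele,
                              .data$alt_alleles, .data$genotypes)
  write_atomic(function(p) write_indel_vcf(vcf_tbl, p,
                 sample_ids = cohort$individual_ids),
               file.path(outdir, "indels.vcf"))
  write_atomic(function(p) readr::write_tsv(loci_table(loci), p,
                                            progress = FALSE),
               file.path(outdir, "loci.tsv"))
  write_atomic(function(p) readr::write_tsv(cohort$q_truth, p,
                                            progress = FALSE),
               file.path(outdir, "q.tsv"))

  primers <- stage("screen", function() {
    cand <- dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i)
      design_candidates(loci[i, ], sim$genome, constraints)))
    if (nrow(cand) == 0L) return(cand)
    screened <- screen_markers(cand, loci, sim$genome, criteria)
    screened |>
      dplyr::filter(.data$pass) |>
      dplyr::group_by(.data$marker_id) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  })
  counts$screened_primer_pairs <- nrow(primers)
  write_atomic(function(p) readr::write_tsv(
    dplyr::select(primers, -dplyr::any_of("reasons")), p, progress = FALSE),
    file.path(outdir, "primers.tsv"))

  bands <- stage("pcr", function() in_silico_pcr(primers, loci))
  counts$bands <- nrow(bands)
  write_atomic(function(p) write_band_matrix(bands, p),
               file.path(outdir, "bands.tsv"))

  mstats <- stage("stats", function() marker_summary(bands))
  counts$markers_scored <- nrow(mstats)
  write_atomic(function(p) readr::write_tsv(as_tibble(mstats), p,
                                            progress = FALSE),
               file.path(outdir, "marker_stats.tsv"))

  div <- stage("diversity", function() {
    d <- nei_distance(individual_allele_freqs(bands))
    list(dist = d, tree = upgma(d), pca = pca_binary(bands),
         kin = kinship(bands))
  })
  write_atomic(function(p) write_newick(div$tree, p),
               file.path(outdir, "tree.nwk"))
  write_atomic(function(p) readr::write_tsv(div$pca$coordinates, p,
                                            progress = FALSE),
               file.path(outdir, "pca.tsv"))
  write_atomic(function(p) readr::write_tsv(
    dplyr::bind_cols(tibble(individual_id = rownames(div$kin)),
                     as_tibble(unclass(div$kin))), p, progress = FALSE),
    file.path(outdir, "kinship.tsv"))

  traits <- stage("traits", function() {
    cfg2 <- config
    # default planted-QTL names ("m001", ...) map positionally onto the
    # locus-backed marker IDs
    avail <- unique(cohort$genotypes$marker_id)
    idx <- match(cfg2$planted_qtl$marker,
                 sprintf("m%03d", seq_along(avail)))
    cfg2$planted_qtl$marker <- ifelse(is.na(idx), cfg2$planted_qtl$marker,
                                      avail[idx])
    simulate_traits(cfg2, cohort)
  })
  write_atomic(function(p) readr::write_tsv(traits, p, progress = FALSE),
               file.path(outdir, "traits.tsv"))

  assoc <- stage("assoc", function() {
    dplyr::bind_rows(
      glm_assoc(bands, traits, q = cohort$q_truth),
      as_tibble(mlm_assoc(bands, traits, k = div$kin)),
      as_tibble(mlm_assoc(bands, traits, k = div$kin, q = cohort$q_truth))
    )
  })
  counts$association_tests <- nrow(assoc)
  write_atomic(function(p) readr::write_tsv(
    dplyr::select(assoc, -"effects"), p, progress = FALSE),
    file.path(outdir, "assoc.tsv"))

  stable <- significant_markers(assoc, alpha = alpha)
  genes_hit <- if (nrow(stable)) {
    anchors <- dplyr::distinct(loci[loci$marker_id %in% stable$marker_id,
                                    c("marker_id", "chrom_id", "anchor_pos")])
    candidate_gene_window(anchors, sim$genes, genome = sim$genome)
  } else {
    candidate_gene_window(loci[0, c("marker_id", "chrom_id", "anchor_pos")],
                          sim$genes)
  }
  counts$stable_markers <- nrow(stable)
  counts$candidate_genes <- nrow(genes_hit)
  write_atomic(function(p) readr::write_tsv(genes_hit, p, progress = FALSE),
               file.path(outdir, "candidates.tsv"))

  artifacts <- c("ref.fa", "genes.gff3", "indels.vcf", "loci.tsv", "q.tsv",
                 "primers.tsv", "bands.tsv", "marker_stats.tsv", "tree.nwk",
                 "pca.tsv", "kinship.tsv", "traits.tsv", "assoc.tsv",
                 "candidates.tsv")
  manifest <- list(
    tool = "indelssr",
    version = as.character(utils::packageVersion("indelssr")),
    seed = config$seed,
    config_hash = digest::digest(config),
    stage_counts = counts,
    checksums = lapply(setNames(nm = artifacts), function(f)
      digest::digest(file = file.path(outdir, f), algo = "md5"))
  )
  write_atomic(function(p) jsonlite::write_json(manifest, p,
    auto_unbox = TRUE, pretty = TRUE), file.path(outdir, "manifest.json"))

  invisible(list(sim = sim, loci = loci, cohort = cohort, primers = primers,
                 bands = bands, marker_stats = mstats, diversity = div,
                 traits = traits, assoc = assoc, stable = stable,
                 candidate_genes = genes_hit, manifest = manifest))
}
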