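# SSR detection, compound merging, InDel co-localization and the
# per-chromosome report.

genome1 <- function(seq) {
  tibble::tibble(chrom_id = "c1", sequence = seq, length = nchar(seq))
}

test_that("detection thresholds per motif length are honored", {
  # mononucleotide: ten copies qualify
  hits <- find_perfect_ssrs(genome1("GGCAAAAAAAAAACGG"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "A")
  expect_equal(hits$n_repeats, 10L)
  expect_equal(c(hits$start, hits$end), c(4L, 13L))
  # nine copies do not
  expect_equal(nrow(find_perfect_ssrs(genome1("GGCAAAAAAAAACGG"))), 0L)
  # dinucleotide: five copies yes, four no
  expect_equal(find_perfect_ssrs(genome1("GCATATATATATGC"))$motif, "AT")
  expect_equal(nrow(find_perfect_ssrs(genome1("GCATATATATGC"))), 0L)
  # trinucleotide at four copies
  tri <- find_perfect_ssrs(genome1(paste0("GG", strrep("ACT", 4), "GG")))
  expect_equal(tri$motif, "ACT")
  expect_equal(tri$n_repeats, 4L)
})

test_that("a tract is reported once, at the smallest motif length", {
  # 10 As: mono, never di "AA"
  hits <- find_perfect_ssrs(genome1(strrep("A", 10)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif_len, 1L)
  # (AT)10 is di, never "ATAT"
  hits <- find_perfect_ssrs(genome1(strrep("AT", 10)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "AT")
})

test_that("N terminates tracts and never enters motifs", {
  hits <- find_perfect_ssrs(genome1("AAAAAANAAAAAA"))
  expect_equal(nrow(hits), 0L)  # two runs of 6, split by N
  hits <- find_perfect_ssrs(genome1(paste0(strrep("A", 10), "N",
                                           strrep("A", 10))))
  expect_equal(nrow(hits), 2L)
  expect_false(any(grepl("N", hits$motif)))
})

test_that("finder matches the brute-force oracle on random sequences", {
  set.seed(421)
  for (rep in 1:40) {
    base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
    # plant a few repeats straddling thresholds
    for (p in sample(seq(10, 350, by = 60), 3)) {
      L <- sample(1:6, 1)
      k <- sample(3:11, 1)
      tract <- strrep(paste(sample(c("A", "C", "G", "T"), L,
                                   replace = TRUE), collapse = ""), k)
      base[p:(p + nchar(tract) - 1)] <- strsplit(tract, "")[[1]]
    }
    seq <- paste(base[1:400], collapse = "")
    got <- find_perfect_ssrs(genome1(seq))
    want <- oracle_ssrs(seq)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$motif, want$motif)
      expect_equal(got$n_repeats, want$n_repeats)
    }
  }
})

# period-7 filler with no 1-6 bp tandem repeat at the detection thresholds
spacer <- function(len) substr(strrep("AACGTCG", ceiling(len / 7) + 1), 1, len)

test_that("compound merging uses a strict 100 bp gap rule", {
  mk <- function(gaps) {
    # chain of (AT)5 tracts separated by repeat-free filler
    parts <- "GG"
    for (i in seq_along(gaps)) {
      parts <- paste0(parts, strrep("AT", 5))
      if (!is.na(gaps[i])) parts <- paste0(parts, spacer(gaps[i]))
    }
    find_perfect_ssrs(genome1(paste0(parts, "GG")))
  }
  two <- mk(c(99, NA))
  merged <- merge_compound(two)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$kind, "compound")
  expect_equal(nrow(merged$members[[1]]), 2L)
  # bp covered by members conserved
  expect_equal(sum(with(merged$members[[1]], end - start + 1L)),
               sum(with(two, end - start + 1L)))

  two_far <- mk(c(100, NA))
  expect_equal(merge_compound(two_far)$kind, c("perfect", "perfect"))

  # chain A -(50)- B -(120)- C -> compound{A,B} + perfect C
  three <- mk(c(50, 120, NA))
  m3 <- merge_compound(three)
  expect_equal(m3$kind, c("compound", "perfect"))
  expect_equal(nrow(m3$members[[1]]), 2L)

  expect_error(merge_compound(two[2:1, ]), "not sorted")
})

test_that("InDel-SSR calling respects the 500 bp window and clipping", {
  seq <- spacer(5000)
  put <- function(seq, at, tract) {
    substr(seq, at, at + nchar(tract) - 1L) <- tract
    seq
  }
  # SSR 300 bp downstream of the anchor: in window
  s <- put(seq, 1300, strrep("AT", 6))
  g <- genome1(s)
  ind <- tibble::tibble(chrom_id = "c1", pos = 1000L, ref_allele = "C",
                        alt_alleles = list("CTT"))
  loci <- call_indel_ssrs(ind, g)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$repeat_class, "di")
  expect_equal(loci$motif, "AT")

  # nearest SSR 600 bp downstream: out of window
  s2 <- put(seq, 1601, strrep("AT", 6))
  expect_equal(nrow(call_indel_ssrs(ind, genome1(s2))), 0L)

  # window clipped at chromosome start still finds the tract
  s3 <- put(seq, 50, strrep("A", 12))
  ind3 <- tibble::tibble(chrom_id = "c1", pos = 200L, ref_allele = "C",
                         alt_alleles = list("CA"))
  loci3 <- call_indel_ssrs(ind3, genome1(s3))
  expect_equal(nrow(loci3), 1L)
  expect_equal(loci3$repeat_class, "mono")

  # anchor beyond chromosome end is an error naming the record
  ind_bad <- tibble::tibble(chrom_id = "c1", pos = 9999L, ref_allele = "C",
                            alt_alleles = list("CA"))
  expect_error(call_indel_ssrs(ind_bad, g), "c1:9999")
})

test_that("every emitted locus has a member SSR within the flank", {
  cfg <- sim_config(seed = 5, n_indels = 30)
  sim <- simulate_genome(cfg)
  loci <- call_indel_ssrs(sim$indel_truth, sim$genome)
  for (i in seq_len(nrow(loci))) {
    d <- with(loci$ssrs[[i]],
              pmax(0L, start - loci$anchor_pos[i], loci$anchor_pos[i] - end))
    expect_lte(min(d), 500L)
  }
})

test_that("repeat classes pool reverse complements but not rotations", {
  mk_locus <- function(cls, motif) {
    tibble::tibble(marker_id = paste0(cls, motif), chrom_id = "c1",
                   anchor_pos = 1L, ref_allele = "A",
                   alt_alleles = list("AT"), repeat_class = cls,
                   motif = motif, ssrs = list(NULL), genotypes = list(NULL))
  }
  loci <- dplyr::bind_rows(
    mk_locus("mono", "A"), mk_locus("mono", "T"),
    mk_locus("di", "AG"), mk_locus("di", "CT"), mk_locus("di", "GA"),
    mk_locus("compound", NA)
  )
  comp <- classify_repeat_types(loci)
  expect_equal(sum(comp$by_class$pct), 100)
  expect_equal(comp$by_class$n[comp$by_class$repeat_class == "mono"], 2L)
  expect_equal(comp$by_class$n[comp$by_class$repeat_class == "compound"], 1L)
  bm <- comp$by_motif
  expect_equal(bm$n[bm$motif_class == "A/T"], 2L)
  expect_equal(bm$n[bm$motif_class == "AG/CT"], 2L)
  expect_equal(bm$n[bm$motif_class == "GA/TC"], 1L)
})

test_that("class percentages follow locus counts", {
  loci <- tibble::tibble(
    marker_id = paste0("m", 1:4), chrom_id = "c1", anchor_pos = 1L,
    ref_allele = "A", alt_alleles = list("AT"),
    repeat_class = c("mono", "mono", "di", "compound"),
    motif = c("A", "A", "AT", NA),
    ssrs = list(NULL), genotypes = list(NULL))
  comp <- classify_repeat_types(loci)
  pct <- setNames(comp$by_class$pct, as.character(comp$by_class$repeat_class))
  expect_equal(unname(pct[c("mono", "di", "compound")]), c(50, 25, 25))
})

test_that("chromosome report arithmetic and summary semantics", {
  counts <- tibble::tibble(
    chrom_id = c("c1", "c2"),
    chrom_len = c(2e6, 1e6),
    n_indels = c(1000L, 0L),
    n_indel_ssrs = c(250L, 0L))
  rep <- chromosome_report(counts = counts)
  expect_equal(rep$density_per_mb, c(125, 0))
  expect_equal(rep$ratio_pct, c(25, 0))
  s <- glance(rep)
  expect_equal(s$total_indel_ssrs, 250L)
  expect_equal(s$mean_density_per_mb, 62.5)  # unweighted mean of densities
  expect_equal(s$overall_ratio_pct, 25)
  expect_error(chromosome_report(counts = dplyr::mutate(counts,
                                                        chrom_len = 0)),
               "zero-length")
})
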