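# Readers for genome-scale formats: FASTA (Biostrings), VCF (vcfR) and
# GFF3 (ape::read.gff). All returned coordinates are 1-based inclusive.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any IUPAC ambiguity code other than `N` is
#' replaced by `N` (with a warning). Duplicate sequence IDs and empty files
#' are errors.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `chrom_id`, `sequence`, `length`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA header IDs: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  s <- toupper(as.character(seqs))
  n_ambig <- sum(vapply(s, function(x)
    nchar(gsub("[ACGTN]", "", x)), numeric(1)))
  if (n_ambig > 0) {
    warn(sprintf("%d non-ACGTN base(s) replaced by N", n_ambig))
    s <- gsub("[^ACGTN]", "N", s)
  }
  tibble(chrom_id = ids, sequence = unname(s), length = unname(nchar(s)))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Tibble with `chrom_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  assert_cols(genome, c("chrom_id", "sequence"))
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$chrom_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read InDel loci from a VCF
#'
#' Keeps only length-polymorphic records: those where at least one ALT
#' allele differs in length from REF by `min_len` or more. SNP-only records
#' are dropped. Record order is preserved. Per-sample genotypes, when
#' present, are parsed into allele-index pairs; malformed genotype fields
#' become missing and are counted in a single warning.
#'
#' @param path Path to a VCF (v4.x) file, sites-only or multi-sample.
#' @param min_len Minimum REF/ALT length difference in bp (default 1).
#' @return A tibble with columns `chrom_id`, `pos` (1-based position of the
#'   first REF base), `ref_allele`, `alt_alleles` (list of character
#'   vectors), and `genotypes` (list of two-column integer matrices of
#'   allele indices, 0 = REF; `NULL` when the VCF has no samples).
#' @export
read_indel_vcf <- function(path, min_len = 1) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom_id = character(), pos = integer(),
                  ref_allele = character(), alt_alleles = list(),
                  genotypes = list()))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  is_indel <- mapply(function(ref, alt) {
    any(abs(nchar(alt) - nchar(ref)) >= min_len)
  }, fix$REF, alts)
  keep <- which(is_indel)

  has_gt <- ncol(v@gt) > 1L && "FORMAT" %in% colnames(v@gt)
  n_bad <- 0L
  genotypes <- vector("list", length(keep))
  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gt)
    for (j in seq_along(keep)) {
      g <- gt[keep[j], ]
      parts <- strsplit(g, "[/|]")
      mat <- t(vapply(parts, function(p) {
        if (length(p) == 2L && !anyNA(suppressWarnings(as.integer(p)))) {
          as.integer(p)
        } else {
          c(NA_integer_, NA_integer_)
        }
      }, integer(2)))
      n_bad <- n_bad + sum(is.na(mat[, 1]) & !is.na(g) & g != "./." & g != ".")
      rownames(mat) <- samples
      genotypes[[j]] <- mat
    }
  } else {
    genotypes <- rep(list(NULL), length(keep))
  }
  if (n_bad > 0L) {
    warn(sprintf("%d malformed genotype field(s) treated as missing", n_bad))
  }
  tibble(
    chrom_id = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref_allele = fix$REF[keep],
    alt_alleles = alts[keep],
    genotypes = genotypes
  )
}

#' Read gene records from GFF3
#'
#' Only `gene`-type features are kept (mRNA and other children are
#' ignored). Coordinates are 1-based inclusive as in the file.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `gene_id`, `chrom_id`, `start`, `end`, `strand`.
#' @export
read_gene_gff <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  g <- ape::read.gff(path, GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", g$attributes)
  tibble(
    gene_id = ids,
    chrom_id = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand)
  )
}

# Minimal single-allele-per-record VCF 4.2 text writer used by the
# synthetic-data generator (plain text so fixtures stay diff-able).
write_indel_vcf <- function(indels, path, sample_ids = NULL) {
  assert_cols(indels, c("chrom_id", "pos", "ref_allele", "alt_alleles"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=indelssr_synthetic",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(sample_ids)
  if (has_gt) header <- c(header, "FORMAT", sample_ids)
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(indels))) {
    row <- c(indels$chrom_id[i], indels$pos[i],
             if (!is.null(indels$marker_id)) indels$marker_id[i] else ".",
             indels$ref_allele[i],
             paste(indels$alt_alleles[[i]], collapse = ","),
             ".", "PASS", ".")
    if (has_gt) {
      gt <- indels$genotypes[[i]]
      gs <- apply(gt, 1, function(a) {
        if (anyNA(a)) "./." else paste(sort(a), collapse = "/")
      })
      row <- c(row, "GT", gs)
    }
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

# Minimal GFF3 writer for synthetic gene annotations.
write_gene_gff <- function(genes, path) {
  assert_cols(genes, c("gene_id", "chrom_id", "start", "end", "strand"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tindelssr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom_id, genes$start, genes$end, genes$strand,
                     genes$gene_id), con)
  invisible(path)
}
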