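# Shared small helpers. All genomic coordinates in this package are 1-based
# inclusive (the native VCF/GFF3 and R convention); see the methods vignette.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAGT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(DNA_COMPLEMENT[chars], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# A motif is primitive when it is not a whole-number power of a shorter
# string; only primitive motifs are reported, so a poly-A run is mono, never
# di "AA".
is_primitive_motif <- function(motif) {
  l <- nchar(motif)
  if (l == 1L) return(TRUE)
  for (p in seq_len(l - 1L)) {
    if (l %% p == 0L &&
        motif == strrep(substr(motif, 1L, p), l %/% p)) {
      return(FALSE)
    }
  }
  TRUE
}

# Canonical label pooling a motif with its reverse complement (never its
# rotations): AG and CT share class "AG/CT", while GA/TC is distinct.
motif_class_label <- function(motif) {
  rc <- revcomp(motif)
  vapply(seq_along(motif), function(i) {
    pair <- sort(c(motif[i], rc[i]))
    paste(pair, collapse = "/")
  }, character(1))
}

REPEAT_CLASS_NAMES <- c("mono", "di", "tri", "tetra", "penta", "hexa")

repeat_class_of <- function(motif_len) {
  REPEAT_CLASS_NAMES[motif_len]
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Seed helper: every source of randomness derives from one base seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

chrom_sequence <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_id)
  if (is.na(i)) abort(sprintf("chromosome '%s' not present in genome", chrom))
  genome$sequence[i]
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_id)
  if (is.na(i)) abort(sprintf("chromosome '%s' not present in genome", chrom))
  genome$length[i]
}
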