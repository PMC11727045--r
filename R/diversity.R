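# Genetic distances, UPGMA clustering, PCA, Evanno delta-K and kinship.

#' Per-unit allele frequencies from a band matrix
#'
#' Treats each individual as a two-allele-sample population (frequencies
#' 0, 0.5, 1 at each marker) under the codominant band reading. Used to
#' feed [nei_distance()] at the individual level.
#'
#' @param bands A `band_matrix` tibble.
#' @return Long tibble `unit`, `marker_id`, `allele`, `freq`.
#' @export
individual_allele_freqs <- function(bands) {
  geno <- bands_to_genotypes(bands)
  geno |>
    dplyr::filter(!is.na(.data$allele1)) |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    dplyr::count(unit = .data$individual_id, .data$marker_id,
                 .data$allele, name = "n") |>
    dplyr::mutate(freq = .data$n / 2) |>
    dplyr::select("unit", "marker_id", "allele", "freq")
}

#' Nei's (1972) standard genetic distance
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` where `Jxy` is the mean over loci of
#' `sum_i x_i y_i` and `Jx`, `Jy` the mean homozygosities. Computed for
#' every pair of units (populations, or individuals via
#' [individual_allele_freqs()]). Loci missing in either unit of a pair are
#' dropped for that pair. `Jxy = 0` gives `D = cap` with a warning.
#'
#' @param freqs Long tibble `unit`, `marker_id`, `allele`, `freq`.
#' @param cap Distance assigned when units share no alleles (default 10).
#' @return A [stats::dist] object (method attribute `"nei1972"`).
#' @export
nei_distance <- function(freqs, cap = 10) {
  assert_cols(freqs, c("unit", "marker_id", "allele", "freq"))
  wide <- freqs |>
    dplyr::mutate(key = paste(.data$marker_id, .data$allele, sep = "\r")) |>
    tidyr::pivot_wider(id_cols = "unit", names_from = "key",
                       values_from = "freq", values_fill = NA)
  units <- wide$unit
  m <- as.matrix(wide[-1])
  loci <- sub("\r.*$", "", colnames(m))
  uloc <- unique(loci)
  # frequencies absent for a typed locus are 0; loci untyped in a unit stay NA
  locus_typed <- vapply(uloc, function(l)
    apply(!is.na(m[, loci == l, drop = FALSE]), 1, any),
    logical(nrow(m)))
  locus_typed <- matrix(locus_typed, nrow = nrow(m),
                        dimnames = list(NULL, uloc))
  locus_of_col <- match(loci, uloc)
  m0 <- m
  m0[is.na(m0)] <- 0
  n <- length(units)
  d <- matrix(0, n, n, dimnames = list(units, units))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- which(locus_typed[i, ] & locus_typed[j, ])
      if (!length(shared)) {
        d[i, j] <- d[j, i] <- cap
        warned <- TRUE
        next
      }
      cols <- locus_of_col %in% shared
      nl <- length(shared)
      jxy <- sum(m0[i, cols] * m0[j, cols]) / nl
      jx <- sum(m0[i, cols]^2) / nl
      jy <- sum(m0[j, cols]^2) / nl
      if (jxy <= 0) {
        d[i, j] <- d[j, i] <- cap
        warned <- TRUE
      } else {
        d[i, j] <- d[j, i] <- max(0, -log(jxy / sqrt(jx * jy)))
      }
    }
  }
  if (warned) warn(sprintf("pair(s) sharing no alleles set to cap = %g", cap))
  structure(as.dist(d), method = "nei1972")
}

#' Dice distance on raw band vectors
#'
#' `1 - 2a / (2a + b + c)` per pair over bands scored in both individuals.
#'
#' @param bands A `band_matrix` tibble.
#' @return A [stats::dist] object (method attribute `"dice_binary"`).
#' @export
dice_distance <- function(bands) {
  bands <- validate_band_matrix(bands)
  inds <- band_individuals(bands)
  m <- as.matrix(bands[inds])
  n <- length(inds)
  d <- matrix(0, n, n, dimnames = list(inds, inds))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      a <- sum(m[ok, i] == 1L & m[ok, j] == 1L)
      b <- sum(m[ok, i] == 1L & m[ok, j] == 0L)
      cc <- sum(m[ok, i] == 0L & m[ok, j] == 1L)
      d[i, j] <- d[j, i] <- if (2 * a + b + cc == 0) 1 else
        1 - 2 * a / (2 * a + b + cc)
    }
  }
  structure(as.dist(d), method = "dice_binary")
}

#' UPGMA clustering
#'
#' Average-linkage agglomeration on a distance matrix, returned as a
#' rooted ultrametric [ape::phylo] tree: a child's branch length equals its
#' parent's merge height / 2 minus its own height / 2, so all root-to-leaf
#' path lengths are equal.
#'
#' @param d A [stats::dist] object (e.g. [nei_distance()]).
#' @return An [ape::phylo] tree.
#' @export
upgma <- function(d) {
  d <- as.dist(d)
  if (anyNA(d) || any(!is.finite(d))) abort("distance matrix contains NaN/Inf")
  hc <- hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' PCA of binary band profiles
#'
#' Missing scores are imputed with the band mean; band columns are
#' centered; coordinates come from the eigendecomposition of the
#' covariance of the centered band vectors. Signs are fixed so that each
#' component's largest-magnitude loading is positive, making results
#' deterministic.
#'
#' @param bands A `band_matrix` tibble (>= 2 individuals).
#' @param n_components Number of components to keep.
#' @return List of class `pca_result`: `coordinates` (tibble,
#'   `individual_id` + `PC1..`), `eigenvalues`, `explained` (variance
#'   fractions, nonincreasing).
#' @export
pca_binary <- function(bands, n_components = 10L) {
  bands <- validate_band_matrix(bands)
  inds <- band_individuals(bands)
  if (length(inds) < 2L) abort("PCA needs >= 2 individuals")
  m <- t(as.matrix(bands[inds]))          # individuals x bands
  storage.mode(m) <- "double"
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) m[na, j] <- mean(m[, j], na.rm = TRUE)
  }
  m <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(m) < 1e-12)) abort("band matrix has zero variance")
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(
    coordinates = dplyr::bind_cols(tibble(individual_id = inds),
                                   as_tibble(coords)),
    eigenvalues = ev[seq_len(k)],
    explained = ev[seq_len(k)] / sum(ev)
  ), class = "pca_result")
}

#' Evanno delta-K from a ln P(D) replicate table
#'
#' For interior K: `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| /
#' sd(L(K))`, computed over replicate runs; the optimal K maximizes deltaK.
#' K values with zero replicate spread get an undefined deltaK (NA, with a
#' warning) and are excluded from the argmax.
#'
#' @param lnp Tibble with columns `K` and `lnp` (and optionally `rep`);
#'   needs >= 3 consecutive K values with >= 2 replicates each.
#' @return Tibble of class `deltak_result` (`K`, `mean_lnp`, `sd_lnp`,
#'   `lprime`, `lsecond`, `delta_k`) with attribute `optimal_k`.
#' @export
evanno_delta_k <- function(lnp) {
  assert_cols(lnp, c("K", "lnp"))
  agg <- lnp |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(mean_lnp = mean(.data$lnp), sd_lnp = sd(.data$lnp),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$K)
  if (nrow(agg) < 3L || any(diff(agg$K) != 1L)) {
    abort("need >= 3 consecutive K values")
  }
  if (any(agg$n_rep < 2L)) abort("need >= 2 replicates per K")
  k <- nrow(agg)
  lprime <- c(NA, diff(agg$mean_lnp))
  lsecond <- c(NA, diff(lprime)[-1], NA)  # |L(K+1) - 2L(K) + L(K-1)| at interior K
  delta <- abs(lsecond) / agg$sd_lnp
  zero_sd <- !is.na(lsecond) & agg$sd_lnp == 0
  if (any(zero_sd)) {
    warn(sprintf("sd(lnP) = 0 at K = %s; deltaK undefined there",
                 paste(agg$K[zero_sd], collapse = ", ")))
    delta[zero_sd] <- NA_real_
  }
  res <- tibble(K = agg$K, mean_lnp = agg$mean_lnp, sd_lnp = agg$sd_lnp,
                lprime = lprime, lsecond = lsecond, delta_k = delta)
  optimal <- if (all(is.na(delta))) NA_integer_ else
    res$K[which.max(delta)]
  structure(res, optimal_k = optimal,
            class = c("deltak_result", class(res)))
}

#' @rdname evanno_delta_k
#' @param x A `deltak_result`.
#' @param ... Unused.
#' @export
glance.deltak_result <- function(x, ...) {
  tibble(optimal_k = attr(x, "optimal_k"),
         max_delta_k = suppressWarnings(max(x$delta_k, na.rm = TRUE)))
}

#' Pairwise kinship from band profiles
#'
#' Default `allele_sharing`: for each pair, the mean over co-scored
#' markers of the shared-allele fraction of the two codominant genotypes
#' (1 identical, 0.5 one allele shared, 0 none), rescaled so the minimum
#' off-diagonal value is 0 and identical genotypes score 1. The
#' `frequency_weighted` option is a centered-dosage covariance estimator
#' (VanRaden-style): `Z Z' / (2 sum p(1-p))` with `Z` the band-dosage
#' matrix centered by twice the band frequency.
#'
#' @param bands A `band_matrix` tibble.
#' @param estimator `"allele_sharing"` or `"frequency_weighted"`.
#' @return Symmetric kinship matrix with individual IDs as dimnames and
#'   attribute `estimator`.
#' @export
kinship <- function(bands, estimator = c("allele_sharing",
                                         "frequency_weighted")) {
  estimator <- match.arg(estimator)
  geno <- bands_to_genotypes(bands)
  inds <- band_individuals(bands)
  scored <- geno |>
    dplyr::filter(!is.na(.data$allele1)) |>
    dplyr::count(.data$individual_id)
  missing_all <- setdiff(inds, scored$individual_id)
  if (length(missing_all)) {
    abort(sprintf("individual(s) missing at all markers: %s",
                  paste(missing_all, collapse = ", ")))
  }
  if (estimator == "allele_sharing") {
    # reshape to marker x individual matrices of alleles
    wide1 <- tidyr::pivot_wider(geno, id_cols = "marker_id",
                                names_from = "individual_id",
                                values_from = "allele1")
    wide2 <- tidyr::pivot_wider(geno, id_cols = "marker_id",
                                names_from = "individual_id",
                                values_from = "allele2")
    m1 <- as.matrix(wide1[inds])
    m2 <- as.matrix(wide2[inds])
    n <- length(inds)
    k <- matrix(1, n, n, dimnames = list(inds, inds))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !is.na(m1[, i]) & !is.na(m1[, j])
        if (!any(ok)) {
          k[i, j] <- k[j, i] <- NA_real_
          next
        }
        s <- shared_allele_fraction(m1[ok, i], m2[ok, i],
                                    m1[ok, j], m2[ok, j])
        k[i, j] <- k[j, i] <- mean(s)
      }
    }
    off <- k[lower.tri(k)]
    mn <- min(off, na.rm = TRUE)
    if (mn < 1) {
      k_res <- (k - mn) / (1 - mn)
      diag(k_res) <- diag(k) # self-sharing stays at scale maximum
      k <- k_res
    }
  } else {
    m <- t(as.matrix(bands[inds]))
    storage.mode(m) <- "double"
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) m[na, j] <- mean(m[, j], na.rm = TRUE)
    }
    p <- colMeans(m) / 2
    keep <- p > 0 & p < 1
    z <- sweep(m[, keep, drop = FALSE], 2, 2 * p[keep], `-`)
    k <- z %*% t(z) / (2 * sum(p[keep] * (1 - p[keep])))
    dimnames(k) <- list(inds, inds)
  }
  structure(k, estimator = estimator)
}

# Fraction of alleles shared between two genotypes (order-free multiset
# intersection / 2), vectorized over loci.
shared_allele_fraction <- function(a1, a2, b1, b2) {
  m11 <- a1 == b1; m12 <- a1 == b2; m21 <- a2 == b1; m22 <- a2 == b2
  best <- pmax(as.integer(m11) + as.integer(m22),
               as.integer(m12) + as.integer(m21))
  best / 2
}
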