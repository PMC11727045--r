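# Independent oracles and small fixture builders shared across tests.

# Brute-force SSR finder: for every start and motif length, count full
# tandem copies by direct substring comparison. Reports maximal tracts of
# primitive motifs at their leftmost phase, exactly the contract of
# find_perfect_ssrs, but by naive enumeration.
oracle_ssrs <- function(seq, params = ssr_params()) {
  n <- nchar(seq)
  out <- list()
  idx <- 0L
  for (L in 1:6) {
    thr <- params$min_repeats[[as.character(L)]]
    if (n < L * thr) next
    for (i in seq_len(n - L * thr + 1L)) {
      motif <- substr(seq, i, i + L - 1L)
      if (grepl("[^ACGT]", motif)) next
      # primitive: no proper divisor period
      prim <- TRUE
      for (p in seq_len(L - 1L)) {
        if (L %% p == 0L &&
            motif == paste(rep(substr(motif, 1L, p), L %/% p),
                           collapse = "")) {
          prim <- FALSE
          break
        }
      }
      if (!prim) next
      # leftmost phase: the base before must not continue the period
      if (i > 1L && substr(seq, i - 1L, i - 1L) == substr(motif, L, L)) next
      k <- 1L
      while (i + (k + 1L) * L - 1L <= n &&
             substr(seq, i + k * L, i + (k + 1L) * L - 1L) == motif) {
        k <- k + 1L
      }
      if (k >= thr) {
        idx <- idx + 1L
        out[[idx]] <- data.frame(start = i, end = i + k * L - 1L,
                                 motif = motif, motif_len = L,
                                 n_repeats = k)
      }
    }
  }
  if (idx == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_len = integer(),
                      n_repeats = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_len), , drop = FALSE]
}

# Definitional PIC double sum, written as explicit loops.
oracle_pic <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (j > i) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

# Random frequency vector with k alleles.
random_freqs <- function(k) {
  x <- stats::rgamma(k, 1)
  x / sum(x)
}

# Random ultrametric tree (as a cophenetic distance matrix + the tree) by
# random sequential coalescence at increasing heights.
random_ultrametric <- function(n) {
  labels <- paste0("t", seq_len(n))
  height <- 0
  groups <- as.list(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(groups) > 1L) {
    height <- height + stats::runif(1, 0.5, 2)
    pick <- sample.int(length(groups), 2L)
    for (a in groups[[pick[1]]]) {
      for (b in groups[[pick[2]]]) {
        d[a, b] <- d[b, a] <- 2 * height
      }
    }
    groups[[pick[1]]] <- c(groups[[pick[1]]], groups[[pick[2]]])
    groups[[pick[2]]] <- NULL
  }
  d
}

# Band matrix from explicit per-band rows (matrix with individual cols).
make_bands <- function(marker_id, band_id, scores) {
  dplyr::bind_cols(
    tibble::tibble(marker_id = marker_id, band_id = band_id),
    tibble::as_tibble(scores)
  )
}

# One-marker band matrix for a cohort of codominant genotypes given as a
# two-column matrix of allele labels.
bands_from_genotypes <- function(geno, marker = "m1") {
  inds <- rownames(geno)
  if (is.null(inds)) inds <- sprintf("i%02d", seq_len(nrow(geno)))
  alleles <- sort(unique(as.vector(geno)))
  m <- vapply(seq_len(nrow(geno)), function(i)
    as.integer(alleles %in% geno[i, ]), integer(length(alleles)))
  m <- matrix(m, nrow = length(alleles), dimnames = list(NULL, inds))
  make_bands(marker, paste0(marker, "_", alleles), m)
}

# Simple mean silhouette for labelled points (euclidean).
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  vals <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(vals)
}

# Maximized log-likelihood of a spherical (shared-variance) Gaussian
# mixture with k components, fit by EM from a k-means start.
gmm_loglik <- function(x, k, n_iter = 60L) {
  n <- nrow(x)
  p <- ncol(x)
  if (k == 1L) {
    mu <- colMeans(x)
    s2 <- sum(sweep(x, 2, mu)^2) / (n * p)
    return(-0.5 * n * p * (log(2 * pi * s2) + 1))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 5L))
  mu <- km$centers
  w <- pmax(km$size / n, 1e-6)
  s2 <- max(km$tot.withinss / (n * p), 1e-8)
  ll <- -Inf
  for (it in seq_len(n_iter)) {
    # E step: log responsibilities under N(mu_k, s2 I)
    logd <- vapply(seq_len(k), function(j) {
      -0.5 * rowSums(sweep(x, 2, mu[j, ])^2) / s2 -
        0.5 * p * log(2 * pi * s2) + log(w[j])
    }, numeric(n))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_ll <- sum(lse)
    resp <- exp(logd - lse)
    # M step
    nk <- pmax(colSums(resp), 1e-8)
    w <- nk / n
    mu <- t(vapply(seq_len(k), function(j)
      colSums(resp[, j] * x) / nk[j], numeric(p)))
    s2 <- max(sum(vapply(seq_len(k), function(j)
      sum(resp[, j] * rowSums(sweep(x, 2, mu[j, ])^2)),
      numeric(1))) / (n * p), 1e-8)
    if (is.finite(ll) && abs(new_ll - ll) < 1e-8) {
      ll <- new_ll
      break
    }
    ll <- new_ll
  }
  ll
}

# Synthetic likelihood table for Evanno's method: spherical Gaussian
# mixture log-likelihood on leading PCA coordinates, with replicate spread
# coming from bootstrap resampling of markers — playing the role of
# independent clustering runs.
lnp_table_from_bands <- function(bands, k_values = 1:6, n_rep = 8L) {
  markers <- unique(bands$marker_id)
  rows <- list()
  for (r in seq_len(n_rep)) {
    keep <- sample(markers, round(0.7 * length(markers)))
    sub <- bands[bands$marker_id %in% keep, , drop = FALSE]
    x <- as.matrix(pca_binary(sub, n_components = 4L)$coordinates[-1])
    for (k in k_values) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(K = k, rep = r, lnp = gmm_loglik(x, k))
    }
  }
  dplyr::bind_rows(rows)
}
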