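# Distances, UPGMA, PCA, Evanno delta-K, kinship.

test_that("Nei distance identities and hand example", {
  fr <- tibble::tibble(
    unit = rep(c("x", "y"), each = 2),
    marker_id = "l1", allele = rep(c("a", "b"), 2),
    freq = c(1, 0, 1, 0))
  d <- nei_distance(fr)
  expect_equal(as.numeric(d), 0)

  fr$freq <- c(1, 0, 0.5, 0.5)
  expect_equal(as.numeric(nei_distance(fr)), 0.5 * log(2),
               tolerance = 1e-12)

  # disjoint alleles at the single locus -> capped
  fr$freq <- c(1, 0, 0, 1)
  expect_warning(d <- nei_distance(fr), "cap")
  expect_equal(as.numeric(d), 10)
})

test_that("Nei distance is invariant to locus order and duplication", {
  set.seed(10)
  freqs <- dplyr::bind_rows(lapply(1:5, function(l) {
    dplyr::bind_rows(lapply(c("u1", "u2", "u3"), function(u) {
      p <- random_freqs(3)
      tibble::tibble(unit = u, marker_id = paste0("l", l),
                     allele = paste0("a", 1:3), freq = p)
    }))
  }))
  d1 <- as.matrix(nei_distance(freqs))
  shuffled <- freqs[sample.int(nrow(freqs)), ]
  d2 <- as.matrix(nei_distance(shuffled))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-12)
  doubled <- dplyr::bind_rows(freqs,
                              dplyr::mutate(freqs,
                                marker_id = paste0(marker_id, "_dup")))
  d3 <- as.matrix(nei_distance(doubled))
  expect_equal(d1, d3[rownames(d1), colnames(d1)], tolerance = 1e-12)
})

test_that("UPGMA reproduces hand agglomeration and the n = 2 cherry", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(as.dist(d))
  cp <- ape::cophenetic.phylo(tree)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 4)
  # A and B form the first cherry at height 1 each
  expect_true(ape::is.ultrametric(tree))

  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(as.dist(d2))
  expect_equal(unname(t2$edge.length), c(1.5, 1.5))

  dn <- d; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(upgma(as.dist(dn)), "NaN")
})

test_that("UPGMA recovers random ultrametric trees exactly", {
  set.seed(99)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    d <- random_ultrametric(n)
    tree <- upgma(as.dist(d))
    cp <- ape::cophenetic.phylo(tree)
    expect_equal(cp[rownames(d), colnames(d)], d, tolerance = 1e-9)
  }
})

test_that("PCA geometry: clusters, duplicates, distance identity", {
  # two clusters of identical individuals separate on PC1
  m <- cbind(matrix(rep(c(1L, 0L, 1L, 0L), 4), 4),
             matrix(rep(c(0L, 1L, 0L, 1L), 4), 4))
  colnames(m) <- sprintf("i%d", 1:8)
  bands <- make_bands(rep("m1", 4), paste0("b", 1:4), m)
  pc <- pca_binary(bands, n_components = 2)
  co <- pc$coordinates
  g1 <- co$PC1[1:4]; g2 <- co$PC1[5:8]
  expect_true(max(abs(diff(g1))) < 1e-10)
  expect_true(max(abs(diff(g2))) < 1e-10)
  expect_gt(abs(g1[1] - g2[1]), 1)

  # full-rank case: PC-space distances equal centered-data distances
  set.seed(5)
  m2 <- matrix(rbinom(60, 1, 0.5), nrow = 6,
               dimnames = list(NULL, sprintf("i%d", 1:10)))
  bands2 <- make_bands(rep("mA", 6), paste0("b", 1:6), m2)
  pc2 <- pca_binary(bands2, n_components = 10)
  x <- scale(t(m2), center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(as.matrix(pc2$coordinates[-1]))),
               as.matrix(dist(x)), tolerance = 1e-8, ignore_attr = TRUE)

  # duplicated individual lands on identical coordinates
  m3 <- cbind(m2, i11 = m2[, 1])
  bands3 <- make_bands(rep("mA", 6), paste0("b", 1:6), m3)
  co3 <- pca_binary(bands3, n_components = 3)$coordinates
  expect_equal(unlist(co3[co3$individual_id == "i11", -1]),
               unlist(co3[co3$individual_id == "i1", -1]),
               tolerance = 1e-10)

  # explained fractions are in [0, 1], nonincreasing
  expect_true(all(diff(pc2$explained) <= 1e-12))
  expect_true(all(pc2$explained >= 0 & pc2$explained <= 1))

  zero <- make_bands("m1", "b1",
                     matrix(1L, 1, 3, dimnames = list(NULL, c("a", "b", "c"))))
  expect_error(pca_binary(zero), "zero variance")
})

test_that("delta-K: zero second difference, constructed kink, invariance", {
  set.seed(1)
  # linear mean lnP with constant noise -> all interior deltaK ~ 0
  lin <- tidyr::expand_grid(K = 1:6, rep = 1:5)
  lin$lnp <- -100 + 10 * lin$K + rep(c(-0.5, -0.25, 0, 0.25, 0.5), 6)
  dk <- evanno_delta_k(lin)
  expect_true(all(abs(dk$delta_k[!is.na(dk$delta_k)]) < 1e-9))

  # kink at K = 3
  kink <- tidyr::expand_grid(K = 1:6, rep = 1:4)
  mean_l <- c(-200, -120, -60, -55, -50, -45)
  kink$lnp <- mean_l[kink$K] + rep(c(-1, -0.5, 0.5, 1), 6)
  dk2 <- evanno_delta_k(kink)
  expect_equal(attr(dk2, "optimal_k"), 3)

  # invariant to adding a constant to all L
  kink2 <- dplyr::mutate(kink, lnp = lnp + 500)
  expect_equal(evanno_delta_k(kink2)$delta_k, dk2$delta_k,
               tolerance = 1e-9)

  # K = 1..10 with 10 replicates gives 8 interior values
  big <- tidyr::expand_grid(K = 1:10, rep = 1:10)
  big$lnp <- -5 * (big$K - 4)^2 + stats::rnorm(nrow(big), sd = 0.3)
  dkb <- evanno_delta_k(big)
  expect_equal(sum(!is.na(dkb$lsecond)), 8L)

  # zero replicate spread is flagged and excluded
  kink$lnp[kink$K == 2] <- -120
  expect_warning(dk3 <- evanno_delta_k(kink), "sd\\(lnP\\) = 0")
  expect_true(is.na(dk3$delta_k[dk3$K == 2]))
})

test_that("allele-sharing kinship scales from 0 to 1", {
  # identical, disjoint, and half-sharing pairs
  geno <- matrix(c("b1", "b1",
                   "b1", "b1",
                   "b2", "b2",
                   "b1", "b2"), ncol = 2, byrow = TRUE,
                 dimnames = list(c("same1", "same2", "disjoint", "half"),
                                 NULL))
  bands <- bands_from_genotypes(geno)
  k <- kinship(bands)
  expect_equal(k["same1", "same2"], 1)
  expect_equal(k["same1", "disjoint"], 0)
  expect_true(isSymmetric(unclass(k)))
  expect_true(all(diag(k) >= rowMeans(k)))
})

test_that("kinship errors on an all-missing individual", {
  m <- matrix(c(1L, 0L, NA, 0L, 1L, NA), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("i1", "i2", "i3")))
  bands <- make_bands(c("m1", "m1"), c("b1", "b2"), m)
  expect_error(kinship(bands), "missing at all markers")
})

test_that("parent-offspring pairs exceed cohort-average kinship", {
  set.seed(123)
  n_mark <- 40
  founders <- lapply(1:10, function(i)
    matrix(sample(paste0("a", 1:4), 2 * n_mark, replace = TRUE), ncol = 2))
  parent <- founders[[1]]
  child <- t(vapply(seq_len(n_mark), function(j) {
    c(parent[j, sample(1:2, 1)],
      founders[[2]][j, sample(1:2, 1)])
  }, character(2)))
  all_geno <- c(founders, list(child))
  bands <- dplyr::bind_rows(lapply(seq_len(n_mark), function(j) {
    g <- t(vapply(all_geno, function(x) sort(x[j, ]), character(2)))
    rownames(g) <- c(sprintf("f%02d", 1:10), "child")
    bands_from_genotypes(g, marker = sprintf("m%02d", j))
  }))
  k <- kinship(bands)
  off <- k[lower.tri(k)]
  expect_gt(k["f01", "child"], mean(off))
})

test_that("three-subpopulation cohorts separate in PCA and peak at K = 3", {
  set.seed(2024)
  n_hit <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(seed = 300 + r, n_individuals = 75, n_markers = 60)
    co <- simulate_cohort(cfg)
    labels <- apply(as.matrix(co$q_truth[-1]), 1, which.max)
    pc <- pca_binary(co$bands, n_components = 2)
    sil <- mean_silhouette(as.matrix(pc$coordinates[-1]), labels)
    if (r == 1L) expect_gt(sil, 0.5)
    dk <- evanno_delta_k(lnp_table_from_bands(co$bands))
    if (identical(attr(dk, "optimal_k"), 3L) ||
        identical(attr(dk, "optimal_k"), 3)) {
      n_hit <- n_hit + 1L
    }
  }
  expect_gte(n_hit / n_rep, 0.8)
})
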