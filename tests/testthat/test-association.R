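# Trait summaries, GLM/MLM association, marker stability, gene windows.

test_that("trait summaries compute CV, ANOVA and correlations", {
  tr <- tibble::tibble(
    individual_id = rep(sprintf("i%d", 1:3), 2),
    trait = "t1", year = rep(c(2021L, 2022L), each = 3),
    value = c(2, 4, 6, 4, 6, 2))
  ts <- trait_summaries(tr)
  row <- ts$per_trait[ts$per_trait$year == 2021, ]
  expect_equal(row$mean, 4)
  expect_equal(row$sd, 2)
  expect_equal(row$cv_pct, 50)
  expect_equal(row$range, 4)
  # identical year distributions -> F ~ 0, p ~ 1
  expect_gt(ts$anova_year$anova_p, 0.99)

  # collinear traits give r = 1 with stars
  tr2 <- dplyr::bind_rows(tr,
    dplyr::mutate(tr, trait = "t2", value = value * 3 + 1))
  cors <- trait_summaries(tr2)$correlations
  expect_equal(cors$r, c(1, 1), tolerance = 1e-12)
  expect_equal(cors$stars, c("**", "**"))
})

test_that("constant traits yield CV 0 and undefined normality", {
  tr <- tibble::tibble(individual_id = sprintf("i%d", 1:5), trait = "t1",
                       year = 2021L, value = 7)
  row <- trait_summaries(tr)$per_trait
  expect_equal(row$cv_pct, 0)
  expect_true(is.na(row$shapiro_w))
})

sim_assoc_data <- function(seed, n = 200, effect = 1, maf = 0.4) {
  set.seed(seed)
  inds <- sprintf("i%03d", seq_len(n))
  dos <- rbinom(n, 2, maf)
  geno <- cbind(ifelse(dos >= 1, "b1", "b2"), ifelse(dos == 2, "b1", "b2"))
  rownames(geno) <- inds
  bands <- bands_from_genotypes(geno, marker = "mQ")
  y <- effect * as.numeric(scale(dos)) + rnorm(n)
  traits <- tibble::tibble(individual_id = inds, trait = "t1",
                           year = 2021L, value = y)
  list(bands = bands, traits = traits, inds = inds)
}

test_that("GLM detects a planted additive effect", {
  d <- sim_assoc_data(101, effect = 1)
  res <- glm_assoc(d$bands, d$traits)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$r2, 0.1)
})

test_that("GLM requires enough individuals", {
  d <- sim_assoc_data(102, n = 200)
  tiny <- d$traits[1:3, ]
  expect_error(glm_assoc(d$bands, tiny), "too few individuals")
})

test_that("monomorphic markers are skipped", {
  d <- sim_assoc_data(103)
  mono <- matrix(1L, 1, 200, dimnames = list(NULL, d$inds))
  bands <- dplyr::bind_rows(d$bands, make_bands("mMono", "bM", mono))
  res <- glm_assoc(bands, d$traits)
  expect_false("mMono" %in% res$marker_id)
})

test_that("MLM with identity kinship collapses to the GLM", {
  d <- sim_assoc_data(104, effect = 0.3)
  KI <- diag(200)
  dimnames(KI) <- list(d$inds, d$inds)
  pg <- glm_assoc(d$bands, d$traits)$p_value
  pm <- mlm_assoc(d$bands, d$traits, k = KI)$p_value
  expect_equal(pm, pg, tolerance = 1e-6)
})

test_that("REML recovers planted heritability", {
  set.seed(55)
  n <- 150
  inds <- sprintf("i%03d", seq_len(n))
  # structured kinship with unit diagonal
  z <- matrix(rnorm(n * 40), n)
  K <- tcrossprod(z) / 40
  K <- K / mean(diag(K))
  dimnames(K) <- list(inds, inds)
  h2 <- 0.5
  e <- eigen(K, symmetric = TRUE)
  e$values[e$values < 0] <- 0
  Khalf <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  ests <- vapply(1:5, function(r) {
    y <- sqrt(h2) * as.numeric(Khalf %*% rnorm(n)) +
      rnorm(n, sd = sqrt(1 - h2))
    names(y) <- inds
    fit <- mlm_null(y, cbind(rep(1, n)), K)
    fit$h2
  }, numeric(1))
  expect_lt(abs(mean(ests) - h2), 0.15)
})

test_that("kinship and structure covariates reduce confounded hits", {
  set.seed(66)
  cfg <- sim_config(seed = 17, n_individuals = 100, n_markers = 60,
                    admixture_alpha = 0.1, subpop_divergence = 0.8,
                    h2_polygenic = 0, n_traits = 1, n_years = 1,
                    planted_qtl = tibble::tibble(marker = character(),
                                                 trait = character(),
                                                 effect = numeric()))
  co <- simulate_cohort(cfg)
  # trait driven purely by subpopulation membership -> everything
  # frequency-differentiated looks associated under the GLM
  qm <- as.matrix(co$q_truth[-1])
  traits <- tibble::tibble(individual_id = co$individual_ids, trait = "t1",
                           year = 2021L,
                           value = qm %*% c(0, 1, 2) + rnorm(100, sd = 0.3))
  k <- kinship(co$bands)
  n_glm <- sum(glm_assoc(co$bands, traits)$p_value < 0.05, na.rm = TRUE)
  res_kq <- mlm_assoc(co$bands, traits, k = k, q = co$q_truth)
  n_kq <- sum(res_kq$p_value < 0.05, na.rm = TRUE)
  expect_lt(n_kq, n_glm)
})

test_that("non-PSD kinship is rejected, mild negatives are clipped", {
  d <- sim_assoc_data(107, n = 30)
  K <- diag(30)
  K[1, 2] <- K[2, 1] <- 2    # indefinite
  dimnames(K) <- list(d$inds[1:30], d$inds[1:30])
  expect_error(mlm_assoc(d$bands, d$traits, k = K), "positive semidefinite")
})

test_that("stable markers need significance in several models", {
  res <- tibble::tibble(
    marker_id = c("m1", "m1", "m2", "m2", "m3"),
    trait = "t1", year = 2021L,
    model = c("GLM", "MLM_K", "GLM", "MLM_K", "GLM"),
    p_value = c(0.01, 0.04, 0.01, 0.2, 0.001),
    r2 = 0.1, effects = list(NULL))
  hits <- significant_markers(res, alpha = 0.05, min_models = 2)
  expect_equal(hits$marker_id, "m1")
  expect_equal(hits$n_models, 2L)
  expect_equal(nrow(significant_markers(res[0, ])), 0L)
  counts <- count_significant(res)
  expect_equal(counts$GLM_2021, 3L)
  expect_equal(counts$MLM_K_2021, 1L)
})

test_that("candidate gene windows honor total/flank modes and bounds", {
  genes <- tibble::tibble(
    gene_id = c("near", "edge_in", "edge_out", "far", "other_chr"),
    chrom_id = c("c1", "c1", "c1", "c1", "c2"),
    start = c(2400000, 2400000 - 100000, 2600000, 4000000, 2400000),
    end = c(2401000, 2401000 - 100000, 2601000, 4001000, 2401000),
    strand = "+")
  genes$start[2] <- 2e6 - 4e5; genes$end[2] <- 2e6 - 4e5 + 1000
  genes$start[3] <- 2e6 + 6e5; genes$end[3] <- 2e6 + 6e5 + 1000
  marker <- tibble::tibble(marker_id = "mk", chrom_id = "c1",
                           anchor_pos = 2e6)
  hit <- candidate_gene_window(marker, genes)   # total 1 Mb = +/- 500 kb
  expect_setequal(hit$gene_id, c("near", "edge_in"))
  # sorted by distance to the anchor (edge_in's end is 399 kb away)
  expect_equal(hit$gene_id, c("edge_in", "near"))
  wide <- candidate_gene_window(marker, genes, mode = "flank")
  expect_true("edge_out" %in% wide$gene_id)
  expect_false("far" %in% wide$gene_id)
  expect_false("other_chr" %in% wide$gene_id)
})

test_that("a planted block of genes is returned in full", {
  set.seed(8)
  inside <- tibble::tibble(
    gene_id = sprintf("in%02d", 1:63), chrom_id = "c1",
    start = sort(sample(seq(1600000, 2490000), 63)))
  inside$end <- inside$start + 500
  outside <- tibble::tibble(gene_id = sprintf("out%02d", 1:10),
                            chrom_id = "c1",
                            start = seq(2600000, 3500000, length.out = 10))
  outside$end <- outside$start + 500
  genes <- dplyr::bind_rows(inside, outside)
  genes$strand <- "+"
  marker <- tibble::tibble(marker_id = "mk", chrom_id = "c1",
                           anchor_pos = 2e6)
  hit <- candidate_gene_window(marker, genes)
  expect_equal(sort(hit$gene_id), sort(inside$gene_id))
  expect_equal(nrow(hit), 63L)
})
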