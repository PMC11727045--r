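# Trait summaries and marker-trait association: fixed-effects GLM and
# kinship mixed models (MLM(K), MLM(K+Q)) with candidate-gene windows.
#
# Marker genotypes enter as band-dosage columns (0/1/2 copies per band
# allele) from the codominant reading, with the last allele column dropped
# for identifiability. Years are always analyzed separately.

#' Summaries of agronomic traits
#'
#' Per trait and year: mean, sd, range (max - min), CV (%) = 100 sd/mean,
#' and Shapiro-Wilk normality W and p (NA for constant traits). Per trait:
#' one-way ANOVA p across years. Pairwise Pearson correlations between
#' traits within each year carry two-sided t-test p-values, starred at
#' 0.05 (*) and 0.01 (**).
#'
#' @param traits Long trait tibble (`individual_id`, `trait`, `year`,
#'   `value`).
#' @return List of class `trait_summary` with tibbles `per_trait`,
#'   `anova_year`, `correlations`.
#' @export
trait_summaries <- function(traits) {
  assert_cols(traits, c("individual_id", "trait", "year", "value"))
  traits <- dplyr::filter(traits, !is.na(.data$value))
  per_trait <- traits |>
    dplyr::group_by(.data$trait, .data$year) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      range = diff(range(.data$value)),
      cv_pct = 100 * sd(.data$value) / mean(.data$value),
      shapiro_w = if (sd(.data$value) > 0 && dplyr::n() >= 3)
        shapiro.test(.data$value)$statistic else NA_real_,
      shapiro_p = if (sd(.data$value) > 0 && dplyr::n() >= 3)
        shapiro.test(.data$value)$p.value else NA_real_,
      .groups = "drop")
  anova_year <- traits |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(anova_p = if (dplyr::n_distinct(.data$year) > 1) {
      anova(aov(value ~ factor(year),
                data = dplyr::pick(dplyr::everything())))[["Pr(>F)"]][1]
    } else NA_real_, .groups = "drop")
  correlations <- traits |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, id_cols = "individual_id",
                                 names_from = "trait",
                                 values_from = "value")
      trs <- setdiff(names(wide), "individual_id")
      if (length(trs) < 2L) return(tibble())
      combs <- utils::combn(trs, 2)
      purrr::map_dfr(seq_len(ncol(combs)), function(i) {
        x <- wide[[combs[1, i]]]; y <- wide[[combs[2, i]]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L) return(tibble())
        ct <- cor.test(x[ok], y[ok])
        tibble(trait1 = combs[1, i], trait2 = combs[2, i],
               r = unname(ct$estimate), p = ct$p.value,
               stars = if (ct$p.value <= 0.01) "**"
                       else if (ct$p.value <= 0.05) "*" else "")
      })
    }) |>
    dplyr::ungroup()
  structure(list(per_trait = per_trait, anova_year = anova_year,
                 correlations = correlations),
            class = "trait_summary")
}

# Band-dosage design columns for every marker: list of n_ind x (Na - 1)
# matrices (last allele dropped for identifiability), rownames individuals,
# NA rows for missing genotypes.
marker_dosages <- function(bands) {
  geno <- bands_to_genotypes(bands)
  inds <- band_individuals(bands)
  lapply(split(geno, geno$marker_id), function(g) {
    g <- g[match(inds, g$individual_id), ]
    alleles <- sort(unique(stats::na.omit(c(g$allele1, g$allele2))))
    if (length(alleles) < 2L) return(NULL)   # monomorphic marker
    use <- alleles[-length(alleles)]
    d <- vapply(use, function(a) {
      (g$allele1 == a) + (g$allele2 == a)
    }, numeric(length(inds)))
    d <- matrix(d, nrow = length(inds),
                dimnames = list(inds, use))
    d
  })
}

# Q-matrix fixed-effect columns (one group dropped for identifiability),
# aligned to `inds`.
q_covariates <- function(q, inds) {
  if (is.null(q)) return(NULL)
  assert_cols(q, "individual_id")
  qm <- as.matrix(q[setdiff(names(q), "individual_id")])
  rownames(qm) <- q$individual_id
  qm <- qm[inds, -ncol(qm), drop = FALSE]
  qm
}

# Partial-F association of one whitened marker block against a whitened
# null design. Returns p, incremental R^2 and per-column effects.
partial_f_test <- function(y, X0, D) {
  fit0 <- stats::lm.fit(X0, y)
  rss0 <- sum(fit0$residuals^2)
  X1 <- cbind(X0, D)
  fit1 <- stats::lm.fit(X1, y)
  p1 <- fit1$rank
  dropped <- sum(is.na(fit1$coefficients[seq(ncol(X0) + 1L, ncol(X1))]))
  df_marker <- ncol(D) - dropped
  n <- length(y)
  if (df_marker < 1L || n - p1 < 1L) {
    return(list(p = NA_real_, r2 = NA_real_, effects = NULL,
                dropped = dropped))
  }
  rss1 <- sum(fit1$residuals^2)
  f <- ((rss0 - rss1) / df_marker) / (rss1 / (n - p1))
  p <- pf(f, df_marker, n - p1, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  eff <- fit1$coefficients[seq(ncol(X0) + 1L, ncol(X1))]
  list(p = p, r2 = if (tss > 0) (rss0 - rss1) / tss else NA_real_,
       effects = eff, dropped = dropped)
}

# Shared GLM/MLM association engine. `U` and `w` define the whitening
# transform y* = sqrt(w) * U'y (identity for the GLM).
assoc_scan <- function(y, X0, dosages, U = NULL, w = NULL, model, trait,
                       year) {
  if (!is.null(U)) {
    y <- crossprod(U, y)
    X0 <- crossprod(U, X0)
  }
  if (!is.null(w)) {
    sw <- sqrt(w)
    y <- y * sw
    X0 <- X0 * sw
  }
  n_dropped <- 0L
  rows <- purrr::imap(dosages, function(D, marker) {
    if (is.null(D)) return(NULL)
    Dm <- D
    if (!is.null(U)) Dm <- crossprod(U, Dm)
    if (!is.null(w)) Dm <- Dm * sqrt(w)
    res <- partial_f_test(as.numeric(y), X0, Dm)
    n_dropped <<- n_dropped + res$dropped
    tibble(marker_id = marker, trait = trait, year = year, model = model,
           p_value = res$p, r2 = res$r2,
           effects = list(res$effects))
  })
  if (n_dropped > 0L) {
    warn(sprintf("%d rank-deficient marker column(s) dropped", n_dropped))
  }
  dplyr::bind_rows(rows)
}

# Align bands/traits/Q to a common individual set for one trait x year.
assoc_frame <- function(bands, traits, trait, yr, q) {
  inds <- band_individuals(bands)
  tv <- traits[traits$trait == trait & traits$year == yr &
                 !is.na(traits$value), ]
  tv <- tv[tv$individual_id %in% inds, ]
  ids <- tv$individual_id
  y <- setNames(tv$value, ids)
  X0 <- cbind(intercept = rep(1, length(ids)))
  qc <- q_covariates(q, ids)
  if (!is.null(qc)) X0 <- cbind(X0, qc)
  list(ids = ids, y = y, X0 = X0)
}

#' Fixed-effects (GLM) marker-trait association
#'
#' Per marker, trait and year: least-squares regression of the trait on
#' the marker's band-dosage columns, plus optional Q-matrix covariates
#' (one group column dropped), tested with a partial F-test of the marker
#' block. Individuals with a missing genotype at a marker are excluded for
#' that marker (complete-case); `r2` is the marker block's incremental
#' variance explained.
#'
#' @param bands A `band_matrix` tibble.
#' @param traits Long trait tibble.
#' @param q Optional Q matrix (tibble with `individual_id` + proportions).
#' @return Tibble `marker_id`, `trait`, `year`, `model = "GLM"`,
#'   `p_value`, `r2`, `effects` (list of named allele-effect vectors).
#' @export
glm_assoc <- function(bands, traits, q = NULL) {
  dosages <- marker_dosages(bands)
  combos <- dplyr::distinct(traits[!is.na(traits$value), ],
                            .data$trait, .data$year)
  res <- purrr::pmap(combos, function(trait, year) {
    fr <- assoc_frame(bands, traits, trait, year, q)
    if (length(fr$ids) < ncol(fr$X0) + 3L) {
      abort(sprintf("too few individuals (%d) for trait '%s' year %s",
                    length(fr$ids), trait, year))
    }
    per_marker <- purrr::imap(dosages, function(D, marker) {
      if (is.null(D)) return(NULL)
      Dm <- D[fr$ids, , drop = FALSE]
      ok <- stats::complete.cases(Dm)
      if (sum(ok) < ncol(fr$X0) + ncol(Dm) + 2L) return(NULL)
      res <- partial_f_test(fr$y[ok], fr$X0[ok, , drop = FALSE],
                            Dm[ok, , drop = FALSE])
      tibble(marker_id = marker, trait = trait, year = year,
             model = "GLM", p_value = res$p, r2 = res$r2,
             effects = list(res$effects))
    })
    dplyr::bind_rows(per_marker)
  })
  dplyr::bind_rows(res)
}

# REML machinery ------------------------------------------------------------

# Eigendecompose a kinship matrix, clipping slightly negative eigenvalues;
# strongly negative ones are an error.
kinship_spectrum <- function(K, tol = 1e-6) {
  if (max(abs(K - t(K))) > 1e-8) abort("kinship matrix is not symmetric")
  e <- eigen(K, symmetric = TRUE)
  lim <- -tol * max(abs(e$values))
  if (any(e$values < lim)) {
    abort("kinship matrix is not positive semidefinite beyond tolerance")
  }
  e$values[e$values < 0] <- 0
  e
}

# Profiled REML criterion (-2 log restricted likelihood up to a constant)
# for y = X beta + u + e, u ~ (0, sigma_u^2 K), at delta = sigma_e^2 /
# sigma_u^2, after rotation by the eigenvectors of K.
reml_neg2ll <- function(log_delta, ys, Xs, d) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  sw <- sqrt(w)
  yw <- ys * sw
  Xw <- Xs * sw
  fit <- stats::lm.fit(Xw, yw)
  n <- length(ys); p <- fit$rank
  rss <- sum(fit$residuals^2)
  xtx <- crossprod(Xw[, !is.na(fit$coefficients), drop = FALSE])
  (n - p) * log(rss / (n - p)) + sum(log(d + delta)) +
    determinant(xtx, logarithm = TRUE)$modulus[1] + (n - p)
}

#' Fit the null kinship mixed model by spectral REML
#'
#' `y = X beta + u + e` with `u ~ (0, sigma_u^2 K)`. K is eigendecomposed
#' once; the variance ratio `delta = sigma_e^2 / sigma_u^2` is profiled by
#' golden-section search over `log(delta)` on `[1e-5, 1e5]`.
#'
#' @param y Named numeric response vector.
#' @param X Fixed-effect design matrix (rows matching `y`).
#' @param K Kinship matrix with matching dimnames.
#' @return Object of class `mlm_fit`: coefficients, `sigma2_u`,
#'   `sigma2_e`, `delta`, `h2` (= sigma_u^2/(sigma_u^2+sigma_e^2)),
#'   restricted log-likelihood (up to constant), and the spectral pieces
#'   reused by [mlm_assoc()].
#' @export
mlm_null <- function(y, X, K) {
  ids <- names(y)
  stopifnot(!is.null(ids), all(ids %in% rownames(K)))
  e <- kinship_spectrum(K[ids, ids])
  U <- e$vectors
  d <- e$values
  ys <- as.numeric(crossprod(U, y))
  Xs <- crossprod(U, X)
  opt <- optimize(reml_neg2ll, interval = log(c(1e-5, 1e5)),
                  ys = ys, Xs = Xs, d = d)
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  fit <- stats::lm.fit(Xs * sqrt(w), ys * sqrt(w))
  sigma2_u <- sum(fit$residuals^2) / (length(ys) - fit$rank)
  structure(list(
    coefficients = fit$coefficients,
    sigma2_u = sigma2_u,
    sigma2_e = delta * sigma2_u,
    delta = delta,
    h2 = 1 / (1 + delta),
    reml_neg2ll = opt$objective,
    spectrum = list(U = U, d = d, w = w, ids = ids)
  ), class = "mlm_fit")
}

#' @rdname mlm_null
#' @param x An `mlm_fit`.
#' @param ... Unused.
#' @export
tidy.mlm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients) %||%
           paste0("b", seq_along(x$coefficients)),
         estimate = unname(x$coefficients))
}

#' @rdname mlm_null
#' @export
glance.mlm_fit <- function(x, ...) {
  tibble(sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e, delta = x$delta,
         h2 = x$h2, reml_neg2ll = x$reml_neg2ll)
}

#' Kinship mixed-model (MLM) marker-trait association
#'
#' `MLM(K)` when `q` is NULL, `MLM(K+Q)` otherwise. The kinship matrix is
#' eigendecomposed once per trait and year; variance components are fitted
#' by REML on the null (no-marker) model and, under the default P3D
#' approximation, held fixed for every marker test (set `p3d = FALSE` for
#' exact per-marker REML). Each marker is tested by a generalized
#' least-squares partial F-test of its dosage block; missing genotypes are
#' imputed with the marker mean so the spectral transform is shared.
#'
#' @param bands A `band_matrix` tibble.
#' @param traits Long trait tibble.
#' @param k Kinship matrix (e.g. from [kinship()]).
#' @param q Optional Q matrix tibble.
#' @param p3d Reuse null-model variance components for all markers
#'   (default) or refit per marker.
#' @return Tibble like [glm_assoc()] with `model` `"MLM_K"` or `"MLM_KQ"`,
#'   plus attribute `fits` (the per-trait/year `mlm_fit` objects).
#' @export
mlm_assoc <- function(bands, traits, k, q = NULL, p3d = TRUE) {
  model <- if (is.null(q)) "MLM_K" else "MLM_KQ"
  dosages <- marker_dosages(bands)
  combos <- dplyr::distinct(traits[!is.na(traits$value), ],
                            .data$trait, .data$year)
  fits <- list()
  res <- purrr::pmap(combos, function(trait, year) {
    fr <- assoc_frame(bands, traits, trait, year, q)
    null_fit <- mlm_null(fr$y, fr$X0, k)
    fits[[paste(trait, year, sep = "/")]] <<- null_fit
    sp <- null_fit$spectrum
    imputed <- lapply(dosages, function(D) {
      if (is.null(D)) return(NULL)
      Dm <- D[fr$ids, , drop = FALSE]
      for (j in seq_len(ncol(Dm))) {
        na <- is.na(Dm[, j])
        if (any(na)) Dm[na, j] <- mean(Dm[, j], na.rm = TRUE)
      }
      Dm
    })
    if (p3d) {
      assoc_scan(fr$y, fr$X0, imputed, U = sp$U, w = sp$w,
                 model = model, trait = trait, year = year)
    } else {
      per_marker <- purrr::imap(imputed, function(Dm, marker) {
        if (is.null(Dm)) return(NULL)
        fit_m <- mlm_null(fr$y, cbind(fr$X0, Dm), k)
        wts <- fit_m$spectrum$w
        ys <- as.numeric(crossprod(sp$U, fr$y)) * sqrt(wts)
        X0s <- crossprod(sp$U, fr$X0) * sqrt(wts)
        Ds <- crossprod(sp$U, Dm) * sqrt(wts)
        out <- partial_f_test(ys, X0s, Ds)
        tibble(marker_id = marker, trait = trait, year = year,
               model = model, p_value = out$p, r2 = out$r2,
               effects = list(out$effects))
      })
      dplyr::bind_rows(per_marker)
    }
  })
  structure(dplyr::bind_rows(res), fits = fits)
}

#' Markers significant across models
#'
#' Keeps marker x trait x year combinations whose p-value passes `alpha`
#' in at least `min_models` models, then markers x traits seen in at least
#' `min_years` years.
#'
#' @param results Row-bound association results from >= 2 models.
#' @param alpha Significance threshold on raw p-values.
#' @param min_models Minimum number of models passing.
#' @param min_years Minimum number of years in which the combination
#'   passes.
#' @return Tibble `marker_id`, `trait`, `year`, `n_models`, `models`,
#'   `min_p`.
#' @export
significant_markers <- function(results, alpha = 0.05, min_models = 2L,
                                min_years = 1L) {
  if (nrow(results) == 0L) {
    return(tibble(marker_id = character(), trait = character(),
                  year = integer(), n_models = integer(),
                  models = character(), min_p = numeric()))
  }
  hits <- results |>
    dplyr::filter(!is.na(.data$p_value), .data$p_value < alpha) |>
    dplyr::group_by(.data$marker_id, .data$trait, .data$year) |>
    dplyr::summarise(n_models = dplyr::n_distinct(.data$model),
                     models = paste(sort(unique(.data$model)),
                                    collapse = ","),
                     min_p = min(.data$p_value), .groups = "drop") |>
    dplyr::filter(.data$n_models >= min_models)
  hits |>
    dplyr::group_by(.data$marker_id, .data$trait) |>
    dplyr::filter(dplyr::n_distinct(.data$year) >= min_years) |>
    dplyr::ungroup()
}

#' Count significant associations per model and year
#'
#' @param results Association results.
#' @param alpha Significance threshold.
#' @return Wide tibble: one row per trait, one column per model/year
#'   combination, cells = number of markers with `p < alpha`.
#' @export
count_significant <- function(results, alpha = 0.05) {
  results |>
    dplyr::filter(!is.na(.data$p_value), .data$p_value < alpha) |>
    dplyr::count(.data$trait, .data$model, .data$year) |>
    tidyr::pivot_wider(names_from = c("model", "year"), values_from = "n",
                       values_fill = 0L)
}

#' Genes within a window around significant markers
#'
#' Returns genes overlapping the window around each marker anchor. With
#' `mode = "total"` (default) the window spans `window_total` bp in total,
#' i.e. anchor +/- `window_total / 2`; with `mode = "flank"` it spans
#' anchor +/- `window_total`. Windows are clipped at chromosome bounds
#' when a genome is supplied; genes are sorted by distance to the anchor.
#'
#' @param markers Tibble with `marker_id`, `chrom_id`, `anchor_pos`.
#' @param genes Gene tibble from [read_gene_gff()].
#' @param window_total Window size in bp (default 1e6).
#' @param mode `"total"` or `"flank"` (see above).
#' @param genome Optional genome tibble for bound clipping.
#' @return Tibble `marker_id`, `gene_id`, `chrom_id`, `start`, `end`,
#'   `strand`, `distance_bp`.
#' @export
candidate_gene_window <- function(markers, genes, window_total = 1e6,
                                  mode = c("total", "flank"),
                                  genome = NULL) {
  mode <- match.arg(mode)
  assert_cols(markers, c("marker_id", "chrom_id", "anchor_pos"))
  half <- if (mode == "total") window_total / 2 else window_total
  out <- purrr::pmap(markers[c("marker_id", "chrom_id", "anchor_pos")],
                     function(marker_id, chrom_id, anchor_pos) {
    lo <- anchor_pos - half
    hi <- anchor_pos + half
    if (!is.null(genome)) {
      lo <- max(1, lo)
      hi <- min(chrom_length(genome, chrom_id), hi)
    }
    g <- genes[genes$chrom_id == chrom_id &
                 genes$end >= lo & genes$start <= hi, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    g$marker_id <- marker_id
    g$distance_bp <- tract_anchor_distance(g$start, g$end, anchor_pos)
    g[order(g$distance_bp), c("marker_id", "gene_id", "chrom_id",
                              "start", "end", "strand", "distance_bp")]
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(marker_id = character(), gene_id = character(),
                  chrom_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  distance_bp = numeric()))
  }
  as_tibble(res)
}
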