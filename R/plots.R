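# ggplot2 views of the main result types.

#' @rdname marker_summary
#' @param object A `marker_stats` tibble.
#' @export
autoplot.marker_stats <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$PIC)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = c(0.25, 0.5), linetype = "dashed") +
    ggplot2::labs(x = "polymorphism information content (PIC)",
                  y = "markers",
                  title = "Marker informativeness",
                  subtitle = "dashed: PIC = 0.25 and 0.5 polymorphism thresholds") +
    ggplot2::theme_minimal()
}

#' @rdname pca_binary
#' @param object A `pca_result`.
#' @param groups Optional named group factor (names = individual IDs).
#' @param ... Unused.
#' @export
autoplot.pca_result <- function(object, groups = NULL, ...) {
  d <- object$coordinates
  if (!is.null(groups)) d$group <- groups[d$individual_id]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' @rdname evanno_delta_k
#' @param object A `deltak_result`.
#' @export
autoplot.deltak_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d[!is.na(d$delta_k), ],
                  ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "optimal_k"),
                        linetype = "dashed") +
    ggplot2::labs(y = expression(Delta * K),
                  title = "Evanno delta-K model choice") +
    ggplot2::theme_minimal()
}

#' @rdname chromosome_report
#' @param object A `chrom_report`.
#' @export
autoplot.chrom_report <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$chrom_id, -.data$density_per_mb),
    y = .data$density_per_mb)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "InDel-SSR density (loci / Mb)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Association p-value overview
#'
#' Faceted -log10(p) dot plot of association results by model.
#'
#' @param results Association result tibble.
#' @param alpha Significance threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_association <- function(results, alpha = 0.05) {
  d <- results[!is.na(results$p_value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker_id,
                                  y = -log10(.data$p_value),
                                  colour = .data$trait)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$model)) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname marker_summary
#' @export
tidy.marker_stats <- function(x, ...) {
  as_tibble(x)
}

#' @rdname evanno_delta_k
#' @export
tidy.deltak_result <- function(x, ...) {
  as_tibble(x)
}

#' @rdname pca_binary
#' @param x A `pca_result`.
#' @export
tidy.pca_result <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, -"individual_id",
                      names_to = "component", values_to = "coordinate")
}

#' @rdname pca_binary
#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_components = length(x$eigenvalues),
         explained_pc1 = x$explained[1],
         explained_pc2 = x$explained[2])
}
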