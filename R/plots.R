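#' Stacked admixture bar plot
#'
#' One bar per sample, filled by group membership proportion — the standard
#' way to display a Q matrix.
#'
#' @param object an `admix_model`.
#' @param order_by group whose membership orders the bars (default the first).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.admix_model <- function(object, order_by = "q1", ...) {
  q <- tidy(object)
  ord <- q |>
    dplyr::filter(.data$group == order_by) |>
    dplyr::arrange(dplyr::desc(.data$proportion)) |>
    dplyr::pull("sample")
  q$sample <- factor(q$sample, levels = ord)
  ggplot2::ggplot(q, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                  fill = .data$group)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Scatter plot of PCA coordinates
#'
#' @param pca result of [pca_genotypes()].
#' @param groups optional group table to colour points.
#' @param dims two component names (default PC1, PC2).
#' @return A ggplot.
#' @export
plot_pca <- function(pca, groups = NULL, dims = c("PC1", "PC2")) {
  sc <- pca$scores
  if (!is.null(groups)) {
    gtab <- if (is.data.frame(groups)) groups else {
      tibble::tibble(sample = names(groups), group = unname(groups))
    }
    sc <- dplyr::left_join(sc, gtab, by = "sample")
  } else {
    sc$group <- "all"
  }
  pct <- round(100 * pca$explained[match(dims, colnames(pca$scores)[-1])], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", dims[1], pct[1]),
                  y = sprintf("%s (%.1f%%)", dims[2], pct[2])) +
    ggplot2::theme_minimal()
}

#' SNP density plot per chromosome
#'
#' @param density tibble from [snp_density()].
#' @return A ggplot.
#' @export
plot_snp_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$bin_start / 1e6,
                                        y = .data$n_snps)) +
    ggplot2::geom_col(width = diff(range(density$bin_start / 1e6)) / 100 + 0.1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "SNPs per bin") +
    ggplot2::theme_minimal()
}
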