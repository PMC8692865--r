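#' Pairwise genotypic r-squared within a physical window
#'
#' For every same-chromosome SNP pair separated by at most `max_dist` bp,
#' r^2 is the squared Pearson correlation of the dosage vectors over
#' pairwise-complete samples. Phase is not required, which suits unphased GBS
#' calls. Pairs with fewer than 4 complete samples or zero variance are
#' skipped.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param group optional group table plus `group_name` to restrict samples.
#' @param group_name group label to keep when `group` is given.
#' @param max_dist maximum pair separation in bp (default 200 kb).
#' @return tibble with `chrom`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(panel, group = NULL, group_name = NULL,
                        max_dist = 200e3) {
  gm <- as_gm(panel)
  if (!is.null(group)) {
    lab <- group_labels(gm, group)
    keep <- if (is.null(group_name)) !is.na(lab) else lab %in% group_name
    gm <- gm_subset(gm, samples = which(keep))
  }
  if (nrow(gm$dosage) < 2L) stop("need at least two samples")
  out <- vector("list", 0)
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < 2L) next
    pos <- gm$sites$pos[idx]
    d <- gm$dosage[, idx, drop = FALSE]
    storage.mode(d) <- "double"
    hi <- findInterval(pos + max_dist, pos)
    for (a in seq_len(length(idx) - 1L)) {
      if (hi[a] <= a) next
      js <- (a + 1L):hi[a]
      x <- d[, a]
      r <- suppressWarnings(stats::cor(x, d[, js, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      n_comp <- colSums(!is.na(x) & !is.na(d[, js, drop = FALSE]))
      r2 <- as.vector(r)^2
      ok <- n_comp >= 4 & !is.na(r2)
      if (!any(ok)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, dist_bp = pos[js[ok]] - pos[a], r2 = r2[ok]
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), dist_bp = integer(),
                          r2 = numeric()))
  }
  dplyr::bind_rows(out)
}

ld_default_breaks <- function(max_dist) {
  unique(c(seq(0, min(20e3, max_dist), by = 1e3),
           if (max_dist > 20e3) seq(25e3, max_dist, by = 5e3), max_dist))
}

#' LD decay curve: mean r-squared per distance bin
#'
#' Bins are half-open on distance; by default 1-kb bins below 20 kb and 5-kb
#' bins beyond, which resolves the short-range crossing typical of GBS panels.
#' Empty bins are omitted.
#'
#' @param pairs tibble from [pairwise_r2()].
#' @param bin_bp single bin width in bp, or `NULL` for the default mixed
#'   scheme.
#' @return An `ld_decay` object: tibble with `bin_start`, `bin_end`,
#'   `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
decay_curve <- function(pairs, bin_bp = NULL) {
  if (nrow(pairs) < 1L) stop("need at least one SNP pair")
  breaks <- if (is.null(bin_bp)) {
    ld_default_breaks(max(pairs$dist_bp) + 1)
  } else {
    seq(0, max(pairs$dist_bp) + bin_bp, by = bin_bp)
  }
  bin <- findInterval(pairs$dist_bp, breaks, rightmost.closed = FALSE)
  tab <- tibble::tibble(bin = bin, r2 = pairs$r2) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(
      bin_start = breaks[.data$bin],
      bin_end = breaks[pmin(.data$bin + 1L, length(breaks))],
      bin_mid = (.data$bin_start + .data$bin_end) / 2
    ) |>
    dplyr::select("bin_start", "bin_end", "bin_mid", "mean_r2", "n_pairs") |>
    dplyr::arrange(.data$bin_start)
  class(tab) <- c("ld_decay", class(tab))
  tab
}

#' LD decay distance at an r-squared threshold
#'
#' Bin means are first made non-increasing by isotonic regression (the decay
#' curve is expected to be monotone; the smoothing is assumption-light and
#' deterministic), then the first crossing below `threshold` is linearly
#' interpolated between the bracketing bin midpoints. If the curve never rises
#' above the threshold the decay distance is 0; if it never falls below, the
#' result is `Inf` (beyond the examined distance) with attribute `max_dist`.
#'
#' @param curve an `ld_decay` from [decay_curve()].
#' @param threshold r-squared threshold (default 0.2).
#' @return decay distance in bp.
#' @export
decay_distance <- function(curve, threshold = 0.2) {
  if (nrow(curve) < 2L) stop("need at least two bins")
  x <- curve$bin_mid
  y <- curve$mean_r2
  iso <- stats::isoreg(x, -y)
  ys <- -iso$yf
  if (ys[1] < threshold) return(0)
  below <- which(ys < threshold)
  if (length(below) == 0L) {
    return(structure(Inf, max_dist = max(curve$bin_end)))
  }
  j <- below[1]
  i <- j - 1L
  x[i] + (ys[i] - threshold) / (ys[i] - ys[j]) * (x[j] - x[i])
}

#' Plot an LD decay curve
#'
#' @param object an `ld_decay` from [decay_curve()].
#' @param threshold r-squared threshold drawn as a horizontal line.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ld_decay <- function(object, threshold = 0.2, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1e3,
                                       y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "Distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
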