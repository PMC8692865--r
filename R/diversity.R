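#' Per-locus gene diversity (expected heterozygosity)
#'
#' GD = 1 - sum(p_i^2) over a locus's allele frequencies. For the biallelic
#' SNPs this pipeline handles the maximum is 0.5 at p = 0.5.
#'
#' @param p numeric vector of allele frequencies at one locus (summing to 1),
#'   or a matrix with one row per locus.
#' @return numeric vector of GD values.
#' @export
gene_diversity <- function(p) {
  if (is.matrix(p)) return(1 - rowSums(p^2))
  1 - sum(p^2)
}

#' Polymorphic information content (Botstein form)
#'
#' PIC = 1 - sum(p_j^2) - sum_{j<k} 2 p_j^2 p_k^2. For biallelic frequencies
#' (p, q) this is 1 - (p^2 + q^2) - 2 p^2 q^2, with maximum 0.375 at p = 0.5.
#'
#' @inheritParams gene_diversity
#' @return numeric vector of PIC values.
#' @export
pic <- function(p) {
  one <- function(pp) {
    s2 <- sum(pp^2)
    cross <- (s2^2 - sum(pp^4)) / 2      # sum_{j<k} p_j^2 p_k^2
    1 - s2 - 2 * cross
  }
  if (is.matrix(p)) apply(p, 1, one) else one(p)
}

#' Shannon's information index at one locus
#'
#' I = -sum(p_i * ln p_i), with 0 * ln 0 taken as 0.
#'
#' @inheritParams gene_diversity
#' @return numeric vector.
#' @export
shannon_index <- function(p) {
  one <- function(pp) {
    pp <- pp[pp > 0]
    -sum(pp * log(pp))
  }
  if (is.matrix(p)) apply(p, 1, one) else one(p)
}

#' Unbiased gene diversity from h and allele-copy count
#'
#' uh = n / (n - 1) * h where n is the number of non-missing allele copies
#' (2 x diploid samples). With n <= 1 the correction is undefined and `NA` is
#' returned.
#'
#' @param h gene diversity.
#' @param n_copies non-missing allele copies at the locus.
#' @return numeric vector.
#' @export
unbiased_gene_diversity <- function(h, n_copies) {
  ifelse(n_copies > 1, n_copies / (n_copies - 1) * h, NA_real_)
}

locus_freq_matrix <- function(gm, samples = NULL) {
  p <- allele_freqs(gm, samples = samples)
  cbind(alt = p, ref = 1 - p)
}

#' Per-locus diversity statistics
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @return tibble with `chrom`, `pos`, `gd`, `pic` per locus.
#' @export
locus_diversity <- function(panel) {
  gm <- as_gm(panel)
  pf <- locus_freq_matrix(gm)
  tibble::tibble(
    chrom = gm$sites$chrom, pos = gm$sites$pos,
    gd = gene_diversity(pf), pic = pic(pf)
  )
}

#' Per-group diversity summary (Na, Ne, h, uh, I)
#'
#' For each group and locus: Na = observed alleles, Ne = 1 / sum(p^2),
#' h = 1 - sum(p^2), uh = n/(n-1) * h with n = non-missing allele copies,
#' I = -sum(p ln p). Group rows are unweighted means over loci. Two pooled
#' rows are reported: `all (mean of groups)` — the unweighted mean of the
#' group rows — and `all (pooled)` — the same statistics computed on all
#' grouped samples pooled, which is the convention that differs for
#' frequency-nonlinear statistics.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param groups group table (see [group_labels()]).
#' @return tibble with `group`, `n`, `na`, `ne`, `h`, `uh`, `i`.
#' @export
group_summary <- function(panel, groups) {
  gm <- as_gm(panel)
  lab <- group_labels(gm, groups)
  gs <- sort(unique(stats::na.omit(lab)))
  if (length(gs) == 0L) stop("no grouped samples")
  one_group <- function(rows) {
    n_samp <- length(rows)
    d <- gm$dosage[rows, , drop = FALSE]
    nc <- 2 * colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    pf <- cbind(p, 1 - p)
    na_l <- rowSums(pf > 0)
    s2 <- rowSums(pf^2)
    h_l <- 1 - s2
    uh_l <- unbiased_gene_diversity(h_l, nc)
    i_l <- shannon_index(pf)
    usable <- nc > 0
    tibble::tibble(
      n = n_samp,
      na = mean(na_l[usable]), ne = mean(1 / s2[usable]),
      h = mean(h_l[usable]),
      uh = if (n_samp >= 2) mean(uh_l[usable]) else NA_real_,
      i = mean(i_l[usable])
    )
  }
  per <- purrr::map_dfr(gs, function(g) {
    dplyr::bind_cols(tibble::tibble(group = g), one_group(which(lab == g)))
  })
  mean_row <- per |>
    dplyr::summarise(dplyr::across(c("na", "ne", "h", "uh", "i"), mean)) |>
    dplyr::mutate(group = "all (mean of groups)", n = sum(per$n), .before = 1)
  pooled <- dplyr::bind_cols(tibble::tibble(group = "all (pooled)"),
                             one_group(which(!is.na(lab))))
  dplyr::bind_rows(per, mean_row, pooled)
}

#' Windowed nucleotide diversity
#'
#' Per half-open window of `window_bp`, pi = sum over SNPs of the unbiased
#' per-site heterozygosity n/(n-1) * 2 p (1-p), divided by the window length
#' in bp (the windowed-pi convention of standard VCF tooling). Windows with no
#' SNPs have pi = 0; only windows containing data are listed, and the group
#' mean is taken over those windows.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param groups optional group table; when given, one curve per group.
#' @param window_bp window width in bp (default 1 kb).
#' @return tibble with `group`, `chrom`, `win_start`, `win_end`, `n_snps`,
#'   `pi`.
#' @export
pi_windows <- function(panel, groups = NULL, window_bp = 1000) {
  gm <- as_gm(panel)
  labs <- if (is.null(groups)) rep("all", nrow(gm$dosage)) else group_labels(gm, groups)
  gs <- sort(unique(stats::na.omit(labs)))
  purrr::map_dfr(gs, function(g) {
    rows <- which(labs == g)
    d <- gm$dosage[rows, , drop = FALSE]
    nc <- 2 * colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    site_pi <- ifelse(nc > 1, nc / (nc - 1) * 2 * p * (1 - p), 0)
    tibble::tibble(
      chrom = gm$sites$chrom,
      win_start = (gm$sites$pos %/% window_bp) * window_bp,
      site_pi = site_pi
    ) |>
      dplyr::group_by(.data$chrom, .data$win_start) |>
      dplyr::summarise(n_snps = dplyr::n(),
                       pi = sum(.data$site_pi) / window_bp, .groups = "drop") |>
      dplyr::mutate(group = g, win_end = .data$win_start + window_bp,
                    .before = 1)
  })
}

#' Mean nucleotide diversity per group
#'
#' @inheritParams pi_windows
#' @return tibble with `group`, `n_windows`, `pi_mean` (mean over windows
#'   containing data).
#' @export
pi_summary <- function(panel, groups = NULL, window_bp = 1000) {
  pi_windows(panel, groups, window_bp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_windows = dplyr::n(), pi_mean = mean(.data$pi),
                     .groups = "drop")
}
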