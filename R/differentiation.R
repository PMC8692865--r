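# Allele-level AMOVA machinery. Each diploid sample contributes its two
# allele copies; the squared Euclidean distance between binary allele rows
# makes the per-group sum of squares reduce, per locus, to n p (1 - p) with
# n the group's non-missing allele copies -- computed directly from counts.
amova_stats <- function(G0, M2, lab) {
  gs <- sort(unique(lab))
  g <- length(gs)
  Z <- outer(lab, gs, "==") * 1
  k <- t(Z) %*% G0                       # group alt-allele copies (g x L)
  m <- t(Z) %*% M2                       # group total allele copies (g x L)
  ss_within <- sum(ifelse(m > 0, k * (m - k) / pmax(m, 1), 0))
  kt <- colSums(k); mt <- colSums(m)
  ss_total <- sum(ifelse(mt > 0, kt * (mt - kt) / pmax(mt, 1), 0))
  ss_among <- ss_total - ss_within
  n <- length(lab)
  df_among <- g - 1L
  df_within <- 2L * n - g
  sizes <- 2 * table(lab)[gs]
  n0 <- (2 * n - sum(sizes^2) / (2 * n)) / df_among
  sigma_within <- ss_within / df_within
  sigma_among <- (ss_among / df_among - sigma_within) / n0
  phi <- if (sigma_among <= 0) 0 else sigma_among / (sigma_among + sigma_within)
  list(ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       sigma_among = max(sigma_among, 0), sigma_within = sigma_within,
       phi_pt = phi)
}

amova_arrays <- function(d) {
  storage.mode(d) <- "double"
  m2 <- 2 * !is.na(d)
  d[is.na(d)] <- 0
  list(G0 = d, M2 = m2)
}

#' Analysis of molecular variance (AMOVA) with a permutation null
#'
#' Partitions the squared Euclidean distances among allele copies (each
#' diploid sample contributes two) among and within groups, derives the
#' variance components by the moment equations for unequal group sizes, and
#' tests PhiPT = sigma2_among / (sigma2_among + sigma2_within) by permuting
#' whole samples between groups (the two allele copies travel together).
#' At the allele level the fixation index estimates Fst directly, so it is
#' comparable with the Weir-Cockerham moment estimate. Missing genotypes
#' simply contribute no allele copies at that locus. The p-value convention
#' is (1 + #{permuted >= observed}) / (n_perm + 1).
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param groups group table (see [group_labels()]).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return An `amova_result`: list with `table` (source, df, SS, variance,
#'   pct), `phi_pt`, `p_value`, `n_perm`.
#' @export
amova <- function(panel, groups, n_perm = 999, seed = 1L) {
  gm <- as_gm(panel)
  lab <- group_labels(gm, groups)
  keep <- which(!is.na(lab))
  lab <- lab[keep]
  if (length(unique(lab)) < 2L) stop("need at least two groups")
  if (any(table(lab) < 2L)) stop("every group needs at least two samples")
  arr <- amova_arrays(gm$dosage[keep, , drop = FALSE])
  obs <- amova_stats(arr$G0, arr$M2, lab)
  p_value <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- amova_stats(arr$G0, arr$M2, sample(lab))
      if (perm$phi_pt >= obs$phi_pt) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (n_perm + 1)
  }
  total_var <- obs$sigma_among + obs$sigma_within
  tab <- tibble::tibble(
    source = c("among_groups", "within_groups", "total"),
    df = c(obs$df_among, obs$df_within, obs$df_among + obs$df_within),
    ss = c(obs$ss_among, obs$ss_within, obs$ss_among + obs$ss_within),
    variance = c(obs$sigma_among, obs$sigma_within, total_var),
    pct = c(variance_percent(c(obs$sigma_among, obs$sigma_within)), 100)
  )
  structure(
    list(table = tab, phi_pt = obs$phi_pt, p_value = p_value,
         n_perm = n_perm, nm = gene_flow(obs$phi_pt)),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: PhiPT = %.4f, p = %s (%d permutations), Nm = %.2f\n",
              x$phi_pt,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 3),
              x$n_perm, x$nm))
  print(x$table)
  invisible(x)
}

#' Tidy an AMOVA table or panel provenance
#'
#' @param x an `amova_result` or `variant_panel`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.amova_result <- function(x, ...) x$table

#' @rdname tidy.amova_result
#' @export
glance.amova_result <- function(x, ...) {
  tibble::tibble(phi_pt = x$phi_pt, p_value = x$p_value, n_perm = x$n_perm,
                 nm = x$nm)
}

#' Percent of total from variance components
#'
#' @param components numeric vector of (non-negative) variance components.
#' @return numeric vector of percentages summing to 100.
#' @export
variance_percent <- function(components) {
  100 * components / sum(components)
}

wc_fst <- function(d, lab) {
  gs <- unique(lab)
  r <- length(gs)
  per_group <- purrr::map(gs, function(g) {
    dd <- d[lab == g, , drop = FALSE]
    list(n = colSums(!is.na(dd)),
         p = colMeans(dd, na.rm = TRUE) / 2,
         h = colMeans(dd == 1L, na.rm = TRUE))
  })
  n_mat <- do.call(rbind, purrr::map(per_group, "n"))
  p_mat <- do.call(rbind, purrr::map(per_group, "p"))
  h_mat <- do.call(rbind, purrr::map(per_group, "h"))
  ok <- colSums(n_mat >= 1) == r
  n_mat <- n_mat[, ok, drop = FALSE]
  p_mat <- p_mat[, ok, drop = FALSE]
  h_mat <- h_mat[, ok, drop = FALSE]
  n_sum <- colSums(n_mat)
  n_bar <- n_sum / r
  n_c <- (n_sum - colSums(n_mat^2) / n_sum) / (r - 1)
  p_bar <- colSums(n_mat * p_mat) / n_sum
  s2 <- colSums(n_mat * sweep(p_mat, 2, p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_mat * h_mat) / n_sum
  usable <- n_bar > 1 & n_c > 0
  a <- (n_bar / n_c) * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                  (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  sum(a[usable]) / sum((a + b + cc)[usable])
}

#' Pairwise group differentiation (PhiPT and Weir-Cockerham Fst)
#'
#' The default Fst is the AMOVA-based PhiPT of each two-group comparison; the
#' Weir-Cockerham multi-locus moment estimate is reported alongside.
#'
#' @inheritParams amova
#' @return tibble with `group_a`, `group_b`, `fst_phipt`, `fst_wc`.
#' @export
pairwise_fst <- function(panel, groups) {
  gm <- as_gm(panel)
  lab <- group_labels(gm, groups)
  gs <- sort(unique(stats::na.omit(lab)))
  if (length(gs) < 2L) stop("need at least two groups")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    idx <- which(lab %in% pr)
    d <- gm$dosage[idx, , drop = FALSE]
    l2 <- lab[idx]
    arr <- amova_arrays(d)
    res <- amova_stats(arr$G0, arr$M2, l2)
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   fst_phipt = res$phi_pt, fst_wc = wc_fst(d, l2))
  })
}

#' Nei's unbiased genetic distance and identity between group pairs
#'
#' Per locus, the within-group gene identity is bias-corrected as
#' Jx = (2 n sum(p^2) - 1) / (2 n - 1) with n the non-missing diploid samples,
#' and the between-group identity is Jxy = sum(p_x p_y) over alleles. The
#' identity is Id = mean(Jxy) / sqrt(mean(Jx) mean(Jy)) over loci typed in
#' both groups, and D = -ln(Id).
#'
#' @inheritParams amova
#' @return tibble with `group_a`, `group_b`, `d`, `id`.
#' @export
nei_distance <- function(panel, groups) {
  gm <- as_gm(panel)
  lab <- group_labels(gm, groups)
  gs <- sort(unique(stats::na.omit(lab)))
  if (length(gs) < 2L) stop("need at least two groups")
  stat <- purrr::map(gs, function(g) {
    dd <- gm$dosage[lab == g, , drop = FALSE]
    n <- colSums(!is.na(dd))
    p <- colMeans(dd, na.rm = TRUE) / 2
    sum_p2 <- p^2 + (1 - p)^2
    jx <- ifelse(n > 0, (2 * n * sum_p2 - 1) / (2 * n - 1), NA_real_)
    list(n = n, p = p, jx = jx)
  })
  names(stat) <- gs
  purrr::map_dfr(utils::combn(gs, 2, simplify = FALSE), function(pr) {
    a <- stat[[pr[1]]]; b <- stat[[pr[2]]]
    ok <- a$n >= 1 & b$n >= 1
    jxy <- a$p[ok] * b$p[ok] + (1 - a$p[ok]) * (1 - b$p[ok])
    id <- mean(jxy) / sqrt(mean(a$jx[ok]) * mean(b$jx[ok]))
    if (!is.finite(id) || id <= 0) stop("pathological identity (Id <= 0)")
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   d = -log(min(id, 1)), id = min(id, 1))
  })
}

#' Island-model gene flow from Fst
#'
#' Nm = ((1 / Fst) - 1) / 4. Fst <= 0 yields `Inf` (unbounded gene flow),
#' not an error.
#'
#' @param fst fixation index in `(0, 1]` (vectorised).
#' @return numeric vector of Nm values.
#' @export
gene_flow <- function(fst) {
  ifelse(fst <= 0, Inf, (1 / fst - 1) / 4)
}

#' Pairwise differentiation summary table
#'
#' One row per group pair with PhiPT, Weir-Cockerham Fst, Nei's unbiased D
#' and identity, and gene flow Nm from PhiPT.
#'
#' @inheritParams amova
#' @return tibble with `group_a`, `group_b`, `fst_phipt`, `fst_wc`, `d`, `id`,
#'   `nm`.
#' @export
differentiation_summary <- function(panel, groups) {
  dplyr::left_join(
    pairwise_fst(panel, groups),
    nei_distance(panel, groups),
    by = c("group_a", "group_b")
  ) |>
    dplyr::mutate(nm = gene_flow(.data$fst_phipt))
}
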