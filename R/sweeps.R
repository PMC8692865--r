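#' Neutral drift scale between two groups
#'
#' Method-of-moments estimate of the variance scale omega of query-population
#' allele-frequency drift around the reference frequency:
#' omega = mean over loci of (p_q - p_r)^2 divided by the mean of
#' p_r (1 - p_r), excluding loci where the reference frequency is 0 or 1.
#' The ratio-of-means form is used because the per-locus ratio has heavy
#' tails when the reference frequency sits near a boundary. When both groups
#' drift from a common ancestor with differentiation F, omega has expectation
#' about 2F / (1 - F) — the actual variance of the query frequency around the
#' reference, which is what the sweep scan's neutral model needs.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param groups group table (see [group_labels()]).
#' @param ref_group,query_group group labels.
#' @return omega (non-negative scalar).
#' @export
estimate_drift <- function(panel, groups, ref_group, query_group) {
  gm <- as_gm(panel)
  lab <- group_labels(gm, groups)
  p_r <- allele_freqs(gm, samples = which(lab %in% ref_group))
  p_q <- allele_freqs(gm, samples = which(lab %in% query_group))
  ok <- !is.na(p_r) & !is.na(p_q) & p_r > 0 & p_r < 1
  if (!any(ok)) stop("no usable loci (reference fixed or missing everywhere)")
  mean((p_q[ok] - p_r[ok])^2) / mean(p_r[ok] * (1 - p_r[ok]))
}

#' Sliding-window scheme over a SNP panel
#'
#' Half-open windows `[k*step, k*step + size)` per chromosome. Windows with
#' fewer than 2 SNPs are skipped; windows holding more than `max_snps` SNPs
#' are downsampled uniformly at random with the given seed so scans are
#' reproducible.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param size,step window size and step in bp.
#' @param max_snps maximum SNPs retained per window.
#' @param seed seed for the downsampling.
#' @return tibble with `chrom`, `start`, `stop`, `snp_idx` (list of locus
#'   column indices), `n_snps`.
#' @export
window_scheme <- function(panel, size = 50e3, step = 10e3, max_snps = 50,
                          seed = 1L) {
  gm <- as_gm(panel)
  if (ncol(gm$dosage) == 0L) stop("empty panel")
  set.seed(seed)
  purrr::map_dfr(unique(gm$sites$chrom), function(ch) {
    idx <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[idx]
    last <- max(0, ceiling((max(pos) - size) / step)) * step
    starts <- seq(0, last, by = step)
    purrr::map_dfr(starts, function(s) {
      inwin <- idx[pos >= s & pos < s + size]
      if (length(inwin) < 2L) return(NULL)
      if (length(inwin) > max_snps) inwin <- sort(sample(inwin, max_snps))
      tibble::tibble(chrom = ch, start = s, stop = s + size,
                     snp_idx = list(inwin), n_snps = length(inwin))
    })
  })
}

hitch_density <- function(grid, boundary_bw) {
  a <- 1 / boundary_bw
  0.5 * stats::dbeta(grid, a, 1) + 0.5 * stats::dbeta(grid, 1, a)
}

#' Composite-likelihood sweep score for one window
#'
#' The neutral model takes the query allele frequency as normal around the
#' reference frequency with variance omega * p_r (1 - p_r), truncated to
#' \[0, 1\] and renormalized. The sweep model at selection parameter s mixes,
#' per SNP, the neutral density (with the escape probability
#' c(d, s) = 1 - exp(-rho d / s), d = distance to window centre) with a
#' hitchhiking density concentrated at the frequency boundaries (an equal
#' mixture of Beta(1/bw, 1) and Beta(1, 1/bw), symmetric in allele
#' relabelling). Each SNP's likelihood integrates the binomial sampling of
#' the observed alt-allele copies over the density; the score is
#' 2 * (max over `s_grid` of the composite log-likelihood minus the neutral
#' one), truncated at 0.
#'
#' @param snps tibble with `dist` (bp to window centre), `p_ref`, `k_q`
#'   (observed query alt copies), `n_q` (query allele copies).
#' @param omega drift scale from [estimate_drift()].
#' @param s_grid selection-parameter grid (default 10 log-spaced points on
#'   `[1e-4, 1e-1]`).
#' @param rho recombination rate per bp (default 1e-8).
#' @param boundary_bw hitchhiking boundary bandwidth (default 0.05).
#' @param n_grid quadrature points on (0, 1).
#' @return list with `score`, `s_hat`, `loglik_neutral`, `loglik_sweep`.
#' @export
xpclr_score <- function(snps, omega, s_grid = 10^seq(-4, -1, length.out = 10),
                        rho = 1e-8, boundary_bw = 0.05, n_grid = 400) {
  if (length(s_grid) == 0L) stop("empty s_grid")
  stopifnot(omega > 0, nrow(snps) >= 2L)
  dg <- 1 / n_grid
  grid <- seq(dg / 2, 1 - dg / 2, by = dg)
  p_r <- pmin(pmax(snps$p_ref, 0.005), 0.995)
  sd_r <- sqrt(omega * p_r * (1 - p_r))
  # per-SNP neutral density over the grid (rows = SNPs), truncated-renormalized
  dens_n <- t(vapply(seq_along(p_r), function(i) {
    d <- stats::dnorm(grid, p_r[i], sd_r[i])
    d / (sum(d) * dg)
  }, numeric(n_grid)))
  h <- hitch_density(grid, boundary_bw)
  h <- h / (sum(h) * dg)
  binom <- t(vapply(seq_len(nrow(snps)), function(i) {
    stats::dbinom(snps$k_q[i], snps$n_q[i], grid)
  }, numeric(n_grid)))
  lik_n <- rowSums(dens_n * binom) * dg
  lik_h <- as.vector(binom %*% h) * dg
  floor_l <- 1e-300
  ll_neutral <- sum(log(pmax(lik_n, floor_l)))
  ll_s <- vapply(s_grid, function(s) {
    c_esc <- 1 - exp(-rho * snps$dist / s)
    sum(log(pmax(c_esc * lik_n + (1 - c_esc) * lik_h, floor_l)))
  }, numeric(1))
  best <- which.max(ll_s)
  list(score = max(0, 2 * (ll_s[best] - ll_neutral)),
       s_hat = s_grid[best],
       loglik_neutral = ll_neutral, loglik_sweep = ll_s[best])
}

#' Cross-population composite-likelihood sweep scan
#'
#' Runs [window_scheme()], scores every window with [xpclr_score()] against
#' the drift scale from [estimate_drift()], and calls merged sweep regions
#' with [call_regions()].
#'
#' @inheritParams estimate_drift
#' @param size,step,max_snps windowing parameters (defaults 50 kb, 10 kb, 50).
#' @param top_fraction,gap region-calling parameters (defaults top 1%,
#'   merge gap 10 kb).
#' @param s_grid,rho,boundary_bw,n_grid scoring parameters, see
#'   [xpclr_score()].
#' @param seed seed for window downsampling.
#' @return list with `windows` (scored tibble), `regions` (tibble from
#'   [call_regions()]), `omega`.
#' @export
scan_sweeps <- function(panel, groups, ref_group, query_group,
                        size = 50e3, step = 10e3, max_snps = 50,
                        top_fraction = 0.01, gap = 10e3,
                        s_grid = 10^seq(-4, -1, length.out = 10),
                        rho = 1e-8, boundary_bw = 0.05, n_grid = 400,
                        seed = 1L) {
  gm <- as_gm(panel)
  lab <- group_labels(gm, groups)
  ref_idx <- which(lab %in% ref_group)
  qry_idx <- which(lab %in% query_group)
  if (length(ref_idx) < 5L || length(qry_idx) < 5L) {
    stop("both groups need at least five samples")
  }
  omega <- estimate_drift(panel, groups, ref_group, query_group)
  omega <- max(omega, 1e-4)
  p_ref <- allele_freqs(gm, samples = ref_idx)
  dq <- gm$dosage[qry_idx, , drop = FALSE]
  k_q <- colSums(dq, na.rm = TRUE)
  n_q <- 2 * colSums(!is.na(dq))
  pos_all <- gm$sites$pos
  wins <- window_scheme(panel, size = size, step = step, max_snps = max_snps,
                        seed = seed)
  if (nrow(wins) == 0L) stop("no windows with at least two SNPs")
  scored <- purrr::pmap_dfr(
    list(wins$snp_idx, wins$start, wins$stop),
    function(idx, win_start, win_stop) {
      centre <- (win_start + win_stop) / 2
      ok <- idx[n_q[idx] > 0 & !is.na(p_ref[idx])]
      if (length(ok) < 2L) {
        return(tibble::tibble(score = NA_real_, s_hat = NA_real_))
      }
      snps <- tibble::tibble(
        dist = abs(pos_all[ok] - centre),
        p_ref = p_ref[ok], k_q = k_q[ok], n_q = n_q[ok]
      )
      res <- xpclr_score(snps, omega, s_grid = s_grid, rho = rho,
                         boundary_bw = boundary_bw, n_grid = n_grid)
      tibble::tibble(score = res$score, s_hat = res$s_hat)
    })
  windows <- dplyr::bind_cols(wins, scored) |>
    dplyr::filter(!is.na(.data$score))
  list(windows = windows,
       regions = call_regions(windows, gm, top_fraction = top_fraction,
                              gap = gap),
       omega = omega)
}

#' Merge top-scoring windows into sweep regions
#'
#' Selects the `ceiling(n * top_fraction)` highest-scoring windows (ties
#' broken by score, then chromosome and position), sorts them, and merges
#' consecutive selected windows on the same chromosome whose interval gap is
#' below `gap` bp. Each region reports the merged extent, the union of member
#' SNPs, the min/max member SNP positions (the data-supported extent), and
#' the mean member-window score.
#'
#' @param windows scored window tibble from [scan_sweeps()].
#' @param gm the scanned [genotype_matrix()] (or `variant_panel`), for SNP
#'   positions.
#' @param top_fraction fraction of windows selected (default 0.01).
#' @param gap maximum bp gap merged (default 10 kb).
#' @return tibble with `region`, `chrom`, `start`, `stop`, `snp_start`,
#'   `snp_stop`, `n_snps`, `n_windows`, `mean_score`.
#' @export
call_regions <- function(windows, gm, top_fraction = 0.01, gap = 10e3) {
  if (nrow(windows) == 0L) stop("need at least one scored window")
  gm <- as_gm(gm)
  k <- ceiling(nrow(windows) * top_fraction)
  sel <- windows |>
    dplyr::arrange(dplyr::desc(.data$score), .data$chrom, .data$start) |>
    dplyr::slice_head(n = k) |>
    dplyr::arrange(.data$chrom, .data$start)
  out <- list()
  for (ch in unique(sel$chrom)) {
    w <- dplyr::filter(sel, .data$chrom == ch)
    cur <- w[1, ]
    members <- list(w[1, ])
    flush <- function(members) {
      m <- dplyr::bind_rows(members)
      snps <- sort(unique(unlist(m$snp_idx)))
      tibble::tibble(
        chrom = ch, start = min(m$start), stop = max(m$stop),
        snp_start = min(gm$sites$pos[snps]), snp_stop = max(gm$sites$pos[snps]),
        n_snps = length(snps), n_windows = nrow(m), mean_score = mean(m$score)
      )
    }
    if (nrow(w) > 1L) {
      for (i in 2:nrow(w)) {
        if (w$start[i] - max(dplyr::bind_rows(members)$stop) < gap) {
          members <- c(members, list(w[i, ]))
        } else {
          out[[length(out) + 1L]] <- flush(members)
          members <- list(w[i, ])
        }
      }
    }
    out[[length(out) + 1L]] <- flush(members)
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(region = paste0(.data$chrom, ".", dplyr::row_number()),
                  .before = 1) |>
    dplyr::ungroup()
}

#' Manhattan-style plot of sweep-scan window scores
#'
#' @param windows scored window tibble from [scan_sweeps()].
#' @param regions optional region tibble to highlight.
#' @return A ggplot.
#' @export
plot_sweep_scan <- function(windows, regions = NULL) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start + .data$stop) / 2e6,
                                    y = .data$score)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "composite-likelihood score") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$stop / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.2)
  }
  p
}
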