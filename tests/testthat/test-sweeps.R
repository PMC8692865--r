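# Independent fine-grid evaluation of the window score, mirroring the model
# definition with plain loops and a much denser quadrature grid.
xpclr_brute <- function(snps, omega, s_grid, rho = 1e-8, boundary_bw = 0.05,
                        n_grid = 20000) {
  dg <- 1 / n_grid
  grid <- seq(dg / 2, 1 - dg / 2, by = dg)
  a <- 1 / boundary_bw
  h <- 0.5 * stats::dbeta(grid, a, 1) + 0.5 * stats::dbeta(grid, 1, a)
  h <- h / (sum(h) * dg)
  lik_n <- numeric(nrow(snps)); lik_h <- numeric(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    pr <- min(max(snps$p_ref[i], 0.005), 0.995)
    dens <- stats::dnorm(grid, pr, sqrt(omega * pr * (1 - pr)))
    dens <- dens / (sum(dens) * dg)
    b <- stats::dbinom(snps$k_q[i], snps$n_q[i], grid)
    lik_n[i] <- sum(dens * b) * dg
    lik_h[i] <- sum(h * b) * dg
  }
  ll_n <- sum(log(lik_n))
  ll_s <- vapply(s_grid, function(s) {
    ce <- 1 - exp(-rho * snps$dist / s)
    sum(log(ce * lik_n + (1 - ce) * lik_h))
  }, numeric(1))
  max(0, 2 * (max(ll_s) - ll_n))
}

test_that("drift scale estimation matches its moment definition", {
  dos <- rbind(matrix(0L, 6, 10), matrix(0L, 6, 10))
  dos[, 1] <- rep(c(0L, 2L), 6)            # polymorphic everywhere needed
  dos[1:6, 2:10] <- rep(c(0L, 1L, 2L), 2)
  dos[7:12, 2:10] <- rep(c(2L, 1L, 0L), 2)
  gm <- genotype_matrix(
    dos,
    tibble::tibble(chrom = "chr1", pos = seq_len(10) * 1000L, ref = "A",
                   alt = "C", qual = 50),
    tibble::tibble(id = sprintf("S%02d", 1:12))
  )
  groups <- data.frame(sample = gm$samples$id,
                       group = rep(c("R", "Q"), each = 6))
  om <- estimate_drift(gm, groups, "R", "Q")
  p_r <- allele_freqs(gm, samples = 1:6)
  p_q <- allele_freqs(gm, samples = 7:12)
  ok <- p_r > 0 & p_r < 1
  expect_equal(om,
               mean((p_q[ok] - p_r[ok])^2) / mean(p_r[ok] * (1 - p_r[ok])))
  # identical groups: omega ~ 0
  gm2 <- gm; gm2$dosage[7:12, ] <- gm2$dosage[1:6, ]
  expect_lt(estimate_drift(gm2, groups, "R", "Q"), 1e-12)
  # allele relabeling invariance
  gm3 <- gm; gm3$dosage <- 2L - gm3$dosage
  expect_equal(estimate_drift(gm3, groups, "R", "Q"), om)
  # both groups drift from the common ancestor, so the variance of the query
  # frequency around the reference is about 2F p(1-p): omega ~ 2F / (1 - F)
  oms <- vapply(1:5, function(s) {
    sim <- sim_two_pops(seed = 50 + s, n_per_pop = 50, n_loci = 2000, F = 0.1)
    estimate_drift(sim$gm, sim$groups, "P1", "P2")
  }, numeric(1))
  target <- 2 * 0.1 / 0.9
  expect_lt(abs(mean(oms) - target), 0.25 * target)
})

test_that("the window scheme tiles chromosomes as specified", {
  pos <- as.integer(seq(1000, 99000, by = 1000))
  gm <- genotype_matrix(
    matrix(sample(0:2, 2 * length(pos), replace = TRUE), nrow = 2),
    tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "C", qual = 50),
    tibble::tibble(id = c("a", "b"))
  )
  w <- window_scheme(gm, size = 50e3, step = 10e3, max_snps = 50)
  expect_equal(w$start, seq(0, 50e3, by = 10e3))   # six full-size windows
  expect_true(all(w$stop - w$start == 50e3))
  # every member SNP lies inside its window
  for (i in seq_len(nrow(w))) {
    p <- gm$sites$pos[w$snp_idx[[i]]]
    expect_true(all(p >= w$start[i] & p < w$stop[i]))
  }
  # cap: a 60-SNP window keeps exactly 50, reproducibly
  w60 <- window_scheme(gm_subset(gm, loci = 1:60), size = 60e3, step = 60e3,
                       max_snps = 50, seed = 3)
  expect_equal(w60$n_snps[1], 50L)
  w60b <- window_scheme(gm_subset(gm, loci = 1:60), size = 60e3, step = 60e3,
                        max_snps = 50, seed = 3)
  expect_identical(w60$snp_idx, w60b$snp_idx)
})

test_that("window scores agree with brute-force quadrature", {
  s_grid <- 10^seq(-4, -1, length.out = 10)
  cases <- list(
    tibble::tibble(dist = c(1000, 20000), p_ref = c(0.4, 0.6),
                   k_q = c(38L, 35L), n_q = c(40L, 40L)),
    tibble::tibble(dist = c(500, 5000, 24000), p_ref = c(0.2, 0.5, 0.8),
                   k_q = c(0L, 39L, 37L), n_q = c(40L, 40L, 38L)),
    tibble::tibble(dist = c(3000, 9000), p_ref = c(0.5, 0.5),
                   k_q = c(20L, 21L), n_q = c(40L, 40L))
  )
  for (snps in cases) {
    for (om in c(0.05, 0.2)) {
      got <- xpclr_score(snps, om, s_grid = s_grid)$score
      want <- xpclr_brute(snps, om, s_grid = s_grid)
      expect_equal(got, want, tolerance = 0.02)
    }
  }
})

test_that("the sweep model nests the neutral model as s -> 0", {
  snps <- tibble::tibble(dist = c(1000, 20000), p_ref = c(0.4, 0.6),
                         k_q = c(38L, 35L), n_q = c(40L, 40L))
  out <- xpclr_score(snps, 0.1, s_grid = 1e-9)
  expect_equal(out$score, 0)
  expect_equal(out$loglik_sweep, out$loglik_neutral, tolerance = 1e-6)
  expect_error(xpclr_score(snps, 0.1, s_grid = numeric(0)), "empty")
})

test_that("region calling selects the top fraction and merges close windows", {
  gm <- genotype_matrix(
    matrix(sample(0:2, 2 * 4, replace = TRUE), nrow = 2),
    tibble::tibble(chrom = "chr1", pos = c(105e3L, 140e3L, 310e3L, 340e3L),
                   ref = "A", alt = "C", qual = 50),
    tibble::tibble(id = c("a", "b"))
  )
  w <- tibble::tibble(
    chrom = "chr1",
    start = c(100e3, 110e3, 300e3),
    stop = c(150e3, 160e3, 350e3),
    snp_idx = list(1:2, 1:2, 3:4),
    n_snps = c(2L, 2L, 2L),
    score = c(50, 40, 45), s_hat = 0.01
  )
  # top fraction 1 keeps all three; overlapping pair merges, distant one not
  reg <- call_regions(w, gm, top_fraction = 1, gap = 10e3)
  expect_equal(nrow(reg), 2)
  r1 <- reg[reg$start == 100e3, ]
  expect_equal(r1$stop, 160e3)
  expect_equal(r1$n_windows, 2L)
  expect_equal(r1$mean_score, 45)
  expect_equal(r1$n_snps, 2L)
  expect_equal(r1$snp_start, 105e3)
  expect_equal(r1$snp_stop, 140e3)
  expect_equal(reg$region, c("chr1.1", "chr1.2"))
  # quantile arithmetic: 1000 windows at top 1% -> exactly 10 selected
  w1000 <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, by = 100e3, length.out = 1000),
    stop = seq(50e3, by = 100e3, length.out = 1000),
    snp_idx = replicate(1000, 1:2, simplify = FALSE),
    n_snps = 2L,
    score = seq_len(1000) / 10, s_hat = 0.01
  )
  reg1000 <- call_regions(w1000, gm, top_fraction = 0.01, gap = 10e3)
  expect_equal(sum(reg1000$n_windows), 10L)
  expect_equal(nrow(reg1000), 10L)        # all far apart -> no merging
})

test_that("stronger sweeps never score lower at the swept window", {
  med_scores <- vapply(c(30e3, 100e3, 300e3), function(strength) {
    scores <- vapply(1:3, function(s) {
      cfg <- sim_config(n_pops = 2, n_per_pop = 25, n_loci = 1500,
                        F = 0.1, admix_alpha = 0.01, missing_rate = 0,
                        chrom_lengths = c(chr1 = 2e6),
                        sweep = list(chrom = "chr1", pos = 1e6,
                                     strength = strength, pop = 2),
                        seed = 60 + s)
      sim <- sim_panel(cfg)
      groups <- data.frame(sample = sim$gm$samples$id,
                           group = paste0("P", sim$truth$pop))
      sc <- scan_sweeps(sim$gm, groups, "P1", "P2", seed = 60 + s)
      at_sweep <- sc$windows[sc$windows$start <= 1e6 & sc$windows$stop > 1e6, ]
      max(at_sweep$score)
    }, numeric(1))
    stats::median(scores)
  }, numeric(1))
  expect_true(all(diff(med_scores) >= 0))
})

test_that("scores are non-negative and a scan finds an injected sweep", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 30, n_loci = 2000,
                    F = 0.1, admix_alpha = 0.01, missing_rate = 0.02,
                    chrom_lengths = c(chr1 = 2.5e6, chr2 = 2.5e6),
                    sweep = list(chrom = "chr1", pos = 1.25e6,
                                 strength = 150e3, pop = 2),
                    seed = 77)
  sim <- sim_panel(cfg)
  groups <- data.frame(sample = sim$gm$samples$id,
                       group = paste0("P", sim$truth$pop))
  sc <- scan_sweeps(sim$gm, groups, "P1", "P2", seed = 77)
  expect_true(all(sc$windows$score >= 0))
  expect_true(all(sc$windows$n_snps <= 50))
  top <- sc$regions[which.max(sc$regions$mean_score), ]
  expect_equal(top$chrom, "chr1")
  expect_true(top$start <= 1.25e6 && top$stop >= 1.25e6)
  expect_error(scan_sweeps(sim$gm, groups, "P1", "nope"), "five samples")
})
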