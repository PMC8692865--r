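# Shared fixtures and small utilities, all built in code.

rmse <- function(a, b) sqrt(mean((a - b)^2))

# Q-matrix RMSE after the best column permutation (label switching).
aligned_q_rmse <- function(q_est, q_true) {
  K <- ncol(q_true)
  perms <- combinat_perms(K)
  min(vapply(perms, function(pr) rmse(q_est[, pr, drop = FALSE], q_true),
             numeric(1)))
}

combinat_perms <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (rest in combinat_perms(K - 1)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(K), i)[rest])
    }
  }
  out
}

# Hand-built 12-site, 5-sample genotype matrix exercising every cascade step.
# Expected survivors (counted by hand before implementation): sites 7-12 and
# samples S1-S4.
#   1,2: indels; 3: triallelic; 4: monomorphic (MAF 0); 5: QUAL 10;
#   6: depth 5 for S1,S2 -> masked -> 40% missing;
#   7-9: S5 missing (-> S5 reaches 50% missing over survivors);
#   7-12: MAF 1/8 among S1-S4, depth 30, QUAL 50.
cascade_fixture_gm <- function() {
  n <- 5L; L <- 12L
  dos <- matrix(0L, n, L)
  depth <- matrix(30L, n, L)
  qual <- rep(50, L)
  # polymorphism at every kept site: S1 heterozygous
  dos[1, ] <- 1L
  dos[, 4] <- 0L                     # monomorphic
  dos[1, 4] <- 0L
  qual[5] <- 10
  depth[1:2, 6] <- 5L
  dos[5, 7:9] <- NA_integer_
  depth[5, 7:9] <- 0L
  sites <- tibble::tibble(
    chrom = "chr1", pos = seq(100L, 1200L, by = 100L),
    ref = c("A", "AT", "A", "A", "A", "A", rep("A", 6)),
    alt = c("AT", "A", "C,T", "C", "C", "C", rep("C", 6)),
    qual = qual
  )
  samples <- tibble::tibble(id = paste0("S", 1:5))
  genotype_matrix(dos, sites, samples, depth = depth)
}

# Two-population panel with a convenient truth-group table.
sim_two_pops <- function(seed, n_per_pop = 50, n_loci = 2000, F = 0.1,
                         admix_alpha = 0.01, missing_rate = 0, ...) {
  cfg <- sim_config(n_pops = 2, n_per_pop = n_per_pop, n_loci = n_loci,
                    F = F, admix_alpha = admix_alpha,
                    missing_rate = missing_rate, seed = seed, ...)
  sim <- sim_panel(cfg)
  sim$groups <- data.frame(sample = sim$gm$samples$id,
                           group = paste0("P", sim$truth$pop))
  sim
}
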