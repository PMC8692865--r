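test_that("K = 1 has the closed-form solution", {
  sim <- sim_two_pops(seed = 41, n_per_pop = 10, n_loci = 100,
                      missing_rate = 0.05)
  fit <- fit_admixture(sim$gm, K = 1)
  expect_true(all(fit$Q == 1))
  p_hat <- allele_freqs(sim$gm)
  expect_equal(as.vector(fit$P), pmin(pmax(p_hat, 1e-6), 1 - 1e-6),
               tolerance = 1e-9)
  # log-likelihood equals the saturated-at-frequency binomial value
  ll <- sum(stats::dbinom(sim$gm$dosage, 2, rep(p_hat, each = 20),
                          log = TRUE), na.rm = TRUE)
  expect_equal(fit$loglik, ll, tolerance = 1e-4)
  expect_error(fit_admixture(sim$gm, K = 0), "K must")
  expect_error(fit_admixture(sim$gm, K = 21), "exceed")
})

test_that("the EM log-likelihood trace never decreases", {
  sim <- sim_two_pops(seed = 42, n_per_pop = 15, n_loci = 300,
                      admix_alpha = 0.3, missing_rate = 0.05)
  fit <- fit_admixture(sim$gm, K = 2, seed = 3, max_iter = 60)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
  expect_equal(rowSums(fit$Q), rep(1, 30), tolerance = 1e-8)
  expect_true(all(fit$P > 0 & fit$P < 1))
})

test_that("admixture proportions are recovered after label alignment", {
  sim <- sim_two_pops(seed = 43, n_per_pop = 30, n_loci = 1500,
                      admix_alpha = 0.3)
  fit <- fit_admixture(sim$gm, K = 2, seed = 1, max_iter = 300)
  expect_lt(aligned_q_rmse(fit$Q, sim$truth$Q), 0.05)
  td <- tidy(fit)
  expect_named(td, c("sample", "group", "proportion"))
  expect_equal(nrow(td), 60 * 2)
  expect_equal(glance(fit)$K, 2)
})

test_that("the Evanno statistic reproduces a hand evaluation", {
  # replicates m-10, m, m+10 per K: sd = 10 exactly, replicate-wise second
  # differences equal the mean second difference
  means <- c(-1000, -600, -580, -575)
  tab <- tidyr::expand_grid(K = 1:4, replicate = 1:3) |>
    dplyr::mutate(loglik = means[K] + c(-10, 0, 10)[replicate])
  dk <- evanno_deltaK(tab)
  expect_true(all(is.na(dk$delta_k[dk$K %in% c(1, 4)])))
  expect_equal(dk$delta_k[dk$K == 2], abs(-580 - 2 * -600 + -1000) / 10)
  expect_equal(dk$delta_k[dk$K == 2], 38)
  expect_equal(dk$delta_k[dk$K == 3], 1.5)
  expect_equal(dk$K[which.max(dk$delta_k)], 2L)
  # invariance to adding a constant to all log-likelihoods
  dk2 <- evanno_deltaK(dplyr::mutate(tab, loglik = loglik + 5000))
  expect_equal(dk2$delta_k, dk$delta_k)
  # linear mean trajectory: interior delta K = 0
  lin <- tidyr::expand_grid(K = 1:4, replicate = 1:3) |>
    dplyr::mutate(loglik = -100 * K + c(-1, 0, 1)[replicate])
  expect_equal(evanno_deltaK(lin)$delta_k[2:3], c(0, 0))
  # zero replicate sd -> infinite with a warning
  const <- tidyr::expand_grid(K = 1:3, replicate = 1:2) |>
    dplyr::mutate(loglik = c(-90, -50, -45)[K])
  expect_warning(dkc <- evanno_deltaK(const), "zero replicate sd")
  expect_true(is.infinite(dkc$delta_k[dkc$K == 2]))
  expect_error(evanno_deltaK(tab[tab$K < 3, ]), "three consecutive")
})

test_that("assignment respects the membership threshold", {
  q <- rbind(c(0.80, 0.15, 0.05),
             c(0.60, 0.40, 0.00),
             c(0.75, 0.20, 0.05),
             c(0.10, 0.15, 0.75))
  model <- structure(
    list(K = 3, Q = q, P = matrix(0.5, 3, 2), loglik = 0,
         sample_ids = paste0("S", 1:4)),
    class = "admix_model"
  )
  out <- assign_groups(model, tau = 0.75)
  expect_equal(out$label, c("Q1", "admixed", "Q1", "Q3"))
  expect_equal(out$max_membership, c(0.80, 0.60, 0.75, 0.75))
  # the stricter figure-caption variant is just a different tau
  out95 <- assign_groups(model, tau = 0.95)
  expect_true(all(out95$label == "admixed"))
})

test_that("PCA separates clusters and is invariant to locus order", {
  base1 <- matrix(rep(c(0L, 2L), each = 25), 5, 10)
  base2 <- matrix(rep(c(2L, 0L), each = 25), 5, 10)
  dos <- rbind(base1, base2)
  gm <- genotype_matrix(
    dos,
    tibble::tibble(chrom = "chr1", pos = seq_len(10) * 10L, ref = "A",
                   alt = "C", qual = 50),
    tibble::tibble(id = sprintf("S%02d", 1:10))
  )
  pca <- pca_genotypes(gm, n_components = 3)
  expect_gt(pca$explained[1], 0.99)
  expect_true(all(sign(pca$scores$PC1[1:5]) != sign(pca$scores$PC1[6:10])))
  # permuting loci leaves coordinates unchanged
  perm <- sample(10)
  gm_p <- genotype_matrix(dos[, perm],
                          dplyr::mutate(gm$sites[perm, ],
                                        pos = seq_len(10) * 10L),
                          gm$samples)
  pca_p <- pca_genotypes(gm_p, n_components = 3)
  expect_equal(pca_p$scores$PC1, pca$scores$PC1, tolerance = 1e-9)
  # simulated two populations separate on PC1
  sim <- sim_two_pops(seed = 44, n_per_pop = 25, n_loci = 500)
  sc <- pca_genotypes(sim$gm)$scores
  km <- stats::kmeans(sc$PC1, 2)
  agree <- max(mean((km$cluster == 1) == (sim$truth$pop == 1)),
               mean((km$cluster == 2) == (sim$truth$pop == 1)))
  expect_gte(agree, 0.95)
})

test_that("the allele-sharing distance counts shared alleles", {
  dos <- rbind(c(0L, 1L, 2L, NA),
               c(0L, 1L, 0L, 1L),
               c(2L, 1L, 2L, 1L))
  gm <- genotype_matrix(
    dos,
    tibble::tibble(chrom = "chr1", pos = 1:4 * 10L, ref = "A", alt = "C",
                   qual = 50),
    tibble::tibble(id = c("a", "b", "c"))
  )
  d <- allele_sharing_dist(gm)
  # a-b over loci 1..3: |0-0| + |1-1| + |2-0| = 2 -> 2 / (2*3)
  expect_equal(d["a", "b"], 2 / 6)
  # a-c over loci 1..3: 2 + 0 + 0 -> 2/6
  expect_equal(d["a", "c"], 2 / 6)
  # b-c over loci 1..4: 2 + 0 + 2 + 0 -> 4/8
  expect_equal(d["b", "c"], 4 / 8)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
})

test_that("neighbor-joining groups clones with full support", {
  set.seed(9)
  proto <- matrix(sample(0:2, 3 * 60, replace = TRUE), nrow = 3)
  dos <- proto[rep(1:3, each = 2), ]
  gm <- genotype_matrix(
    dos,
    tibble::tibble(chrom = "chr1", pos = seq_len(60) * 10L, ref = "A",
                   alt = "C", qual = 50),
    tibble::tibble(id = paste0("t", 1:6))
  )
  out <- nj_tree(gm, n_boot = 50, seed = 2)
  expect_s3_class(out$tree, "phylo")
  expect_match(out$newick, "^\\(")
  # clones sit at zero path distance; distinct prototypes do not
  d <- allele_sharing_dist(gm)
  expect_equal(d["t1", "t2"], 0)
  coph <- ape::cophenetic.phylo(out$tree)
  pairs <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"))
  for (pr in pairs) {
    expect_lt(coph[pr[1], pr[2]], 1e-8)
  }
  expect_gt(min(coph["t1", "t3"], coph["t1", "t5"], coph["t3", "t5"]), 0.1)
  expect_true(any(out$tree$node.label >= 0.99))
  expect_error(nj_tree(gm_subset(gm, samples = 1:2)), "three")
})
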