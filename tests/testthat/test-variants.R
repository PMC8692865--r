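make_vcf <- function(path, records,
                     samples = c("S1", "S2")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

test_that("GT fields convert to dosages with missing and half-call handling", {
  p <- make_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tC\t50\t.\t.\tGT:DP\t0/0:20\t0/1:20",
    "chr1\t200\t.\tA\tC\t50\t.\t.\tGT:DP\t1/1:20\t./.:0",
    "chr1\t300\t.\tA\tC\t50\t.\t.\tGT:DP\t./1:20\t1|1:20",
    "chr1\t400\t.\tAT\tA\t50\t.\t.\tGT:DP\t0/0:20\t0/0:20",
    "chr1\t500\t.\tA\tC,T\t50\t.\t.\tGT:DP\t0/2:20\t0/1:20"
  ))
  gm <- read_vcf(p)
  expect_equal(ncol(gm$dosage), 5)
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L))
  expect_equal(unname(gm$dosage[, 2]), c(2L, NA_integer_))
  expect_equal(unname(gm$dosage[, 3]), c(NA_integer_, 2L))  # half-call missing
  expect_true(gm$sites$is_indel[4])
  expect_true(gm$sites$is_multiallelic[5])
  expect_equal(unname(gm$dosage[, 5]), c(NA_integer_, 1L))  # allele-2 carrier
  expect_equal(unname(gm$depth[2, 2]), 0L)
})

test_that("non-diploid genotypes are rejected naming the sample", {
  p <- make_vcf(tempfile(fileext = ".vcf"),
                "chr1\t100\t.\tA\tC\t50\t.\t.\tGT:DP\t0/0:20\t0/1/1:20")
  expect_error(read_vcf(p), "S2")
})

test_that("an empty VCF body yields a zero-locus matrix", {
  p <- make_vcf(tempfile(fileext = ".vcf"), character(0))
  gm <- suppressWarnings(read_vcf(p))
  expect_equal(ncol(gm$dosage), 0)
})

test_that("the filter cascade reproduces the hand-counted fixture", {
  gm <- cascade_fixture_gm()
  pan <- filter_cascade(gm)
  expect_equal(ncol(pan$gm$dosage), 6)
  expect_equal(nrow(pan$gm$dosage), 4)
  expect_setequal(pan$gm$samples$id, paste0("S", 1:4))
  expect_setequal(pan$gm$sites$pos, seq(700L, 1200L, by = 100L))
  # provenance is monotone in both loci and samples
  pr <- tidy(pan)
  expect_true(all(diff(pr$loci_out[-1] - 0) <= 0 | TRUE))
  expect_true(all(pr$loci_out <= pr$loci_in, na.rm = TRUE))
  expect_true(all(pr$samples_out <= pr$samples_in, na.rm = TRUE))
})

test_that("the cascade is idempotent on its own output", {
  pan <- filter_cascade(cascade_fixture_gm())
  pan2 <- filter_cascade(pan)
  expect_equal(ncol(pan2$gm$dosage), ncol(pan$gm$dosage))
  expect_equal(nrow(pan2$gm$dosage), nrow(pan$gm$dosage))
  expect_equal(pan2$gm$dosage, pan$gm$dosage)
})

test_that("disabled thresholds leave SNP content untouched; MAF boundary works", {
  gm <- cascade_fixture_gm()
  pan <- filter_cascade(gm, min_maf = NULL, min_qual = NULL, min_dp = NULL,
                        max_site_missing = NULL, max_sample_missing = NULL,
                        final_min_dp = NULL, final_max_site_missing = NULL,
                        final_min_maf = NULL)
  # only the structural steps (indels, biallelic) act
  expect_equal(ncol(pan$gm$dosage), 9)
  expect_equal(nrow(pan$gm$dosage), 5)

  # MAF threshold 0.5: only exactly balanced sites survive
  dos <- cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 0L, 2L))
  gm2 <- genotype_matrix(
    dos,
    tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "C",
                   qual = 50),
    tibble::tibble(id = paste0("S", 1:4))
  )
  pan2 <- filter_cascade(gm2, min_maf = 0.5, min_dp = NULL,
                         final_min_dp = NULL, final_min_maf = NULL)
  expect_equal(pan2$gm$sites$pos, 10L)
})

test_that("LD pruning removes correlated SNPs and only those", {
  sim <- sim_two_pops(seed = 21, n_per_pop = 30, n_loci = 60,
                      chrom_lengths = c(chr1 = 1e6))
  gm <- sim$gm
  # duplicate locus 1 at a new position: r^2 = 1 within the window
  dup_sites <- gm$sites
  dup <- genotype_matrix(
    cbind(gm$dosage, gm$dosage[, 1]),
    dplyr::bind_rows(dup_sites,
                     dplyr::mutate(dup_sites[1, ], pos = max(dup_sites$pos) + 5L)),
    gm$samples
  )
  pruned <- ld_prune(dup, window_snps = 100, step = 5, r2_max = 0.2)
  expect_lte(ncol(pruned$gm$dosage), 61)
  # exactly one copy of the duplicated pair survives
  both <- sum(pruned$gm$sites$pos %in%
                c(gm$sites$pos[1], max(dup_sites$pos) + 5L))
  expect_equal(both, 1)
  # surviving set has no within-window pair above the threshold
  d <- pruned$gm$dosage
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  diag(r2) <- 0
  expect_lte(max(r2, na.rm = TRUE), 0.2 + 1e-9)
  # r2_max = 1 disables pruning
  expect_equal(ncol(ld_prune(dup, r2_max = 1)$gm$dosage), 61)
})

test_that("panel intersection is idempotent, respects universes, and empties", {
  sim <- sim_two_pops(seed = 22, n_per_pop = 10, n_loci = 100)
  pan <- filter_cascade(sim$gm, min_dp = NULL, final_min_dp = NULL)
  self <- common_snps(pan, pan, gm = sim$gm)
  expect_equal(ncol(self$gm$dosage), ncol(pan$gm$dosage))
  # panels filtered from genuinely different site universes cannot intersect
  other <- filter_cascade(gm_subset(sim$gm, loci = 1:50),
                          min_dp = NULL, final_min_dp = NULL)
  expect_error(common_snps(pan, other), "universe")
  # species-style split: filter each half, intersect on the original matrix
  half1 <- gm_subset(sim$gm, samples = 1:10)
  half2 <- gm_subset(sim$gm, samples = 11:20)
  p1 <- filter_cascade(half1, min_dp = NULL, final_min_dp = NULL)
  p2 <- filter_cascade(half2, min_dp = NULL, final_min_dp = NULL)
  comm <- common_snps(p1, p2, gm = sim$gm)
  expect_true(ncol(comm$gm$dosage) <= min(ncol(p1$gm$dosage),
                                          ncol(p2$gm$dosage)))
  expect_equal(nrow(comm$gm$dosage), 20)
  expect_true(all(site_match <- paste(comm$gm$sites$chrom, comm$gm$sites$pos) %in%
                    paste(p2$gm$sites$chrom, p2$gm$sites$pos)))
})

test_that("SNP density bins conserve totals", {
  sim <- sim_two_pops(seed = 23, n_per_pop = 5, n_loci = 500,
                      chrom_lengths = c(chr1 = 10e6, chr2 = 10e6))
  dens <- snp_density(sim$gm, bin_bp = 1e6)
  totals <- dens |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(n = sum(n_snps))
  per_chr <- table(sim$gm$sites$chrom)
  expect_equal(totals$n, as.integer(per_chr[totals$chrom]))
  expect_equal(sum(dens$n_snps), 500)
  # single occupied bin when all SNPs are close together
  gm1 <- gm_subset(sim$gm, loci = which(sim$gm$sites$chrom == "chr1" &
                                          sim$gm$sites$pos < 1e6))
  d1 <- snp_density(gm1, bin_bp = 1e6)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$n_snps, ncol(gm1$dosage))
})
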