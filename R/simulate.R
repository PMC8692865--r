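#' Configuration for the synthetic genotype generator
#'
#' Defines a panel of diploid samples drawn from `n_pops` latent populations
#' whose allele frequencies follow the Balding-Nichols model: an ancestral
#' frequency p is drawn uniformly on \[0.05, 0.95\] and each population's
#' frequency from Beta(p(1-F)/F, (1-p)(1-F)/F), so the expected Fst across
#' loci is approximately `F`. Individuals carry Dirichlet(`admix_alpha`)
#' admixture proportions; genotypes are binomial draws from the mixed
#' frequencies. An optional selective sweep pushes frequencies in one
#' population toward fixation around a focal position before the genotype
#' draw.
#'
#' @param n_pops number of latent populations (2-3 is typical).
#' @param n_per_pop samples per population; scalar or length-`n_pops` vector.
#' @param n_loci number of biallelic SNP loci.
#' @param chrom_lengths named or unnamed vector of chromosome lengths in bp.
#'   Default six 100-Mb chromosomes, matching a 2n = 2x = 12 karyotype.
#' @param F drift parameter in (0, 1); the target Fst of the panel.
#' @param admix_alpha scalar Dirichlet concentration; large values give
#'   near-uniform mixtures, small values near-pure ancestry.
#' @param sweep `NULL` or a list with `chrom`, `pos` (bp), `strength`
#'   (length scale in bp of the frequency push), `pop` (affected population
#'   index).
#' @param missing_rate fraction of genotypes set missing completely at random.
#' @param depth_mean,depth_size mean and dispersion (size) of the negative
#'   binomial per-genotype read depth.
#' @param qual_mean mean site quality score (QUAL).
#' @param contaminant_fraction fraction of emitted VCF records that are indels
#'   or multiallelic, to exercise the filter cascade.
#' @param seed integer seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 2, n_per_pop = 50, n_loci = 5000,
                       chrom_lengths = rep(100e6, 6),
                       F = 0.1, admix_alpha = 0.01,
                       sweep = NULL, missing_rate = 0.02,
                       depth_mean = 30, depth_size = 5,
                       qual_mean = 60, contaminant_fraction = 0,
                       seed = 1L) {
  if (!is.numeric(F) || F <= 0 || F >= 1) stop("F must lie in (0, 1)")
  if (n_loci < 1) stop("n_loci must be at least 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must lie in [0, 1)")
  }
  n_per_pop <- rep_len(n_per_pop, n_pops)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (!is.null(sweep)) {
    stopifnot(all(c("chrom", "pos", "strength", "pop") %in% names(sweep)))
    if (!sweep$chrom %in% names(chrom_lengths)) {
      stop("sweep chromosome not in the map")
    }
    if (sweep$pos < 1 || sweep$pos > chrom_lengths[[sweep$chrom]]) {
      stop("sweep position outside the chromosome")
    }
    if (sweep$pop < 1 || sweep$pop > n_pops) stop("sweep population index out of range")
  }
  structure(
    list(
      n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
      n_loci = as.integer(n_loci), chrom_lengths = chrom_lengths,
      F = F, admix_alpha = admix_alpha, sweep = sweep,
      missing_rate = missing_rate, depth_mean = depth_mean,
      depth_size = depth_size, qual_mean = qual_mean,
      contaminant_fraction = contaminant_fraction, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Genomic map for a simulated panel
#'
#' Loci are allocated to chromosomes proportionally to length and placed at
#' sorted uniform positions, unique within each chromosome.
#'
#' @param cfg a [sim_config()].
#' @return tibble with columns `chrom`, `pos`.
#' @keywords internal
sim_map <- function(cfg) {
  len <- cfg$chrom_lengths
  n_chr <- floor(cfg$n_loci * len / sum(len))
  rem <- cfg$n_loci - sum(n_chr)
  if (rem > 0) {
    take <- order(cfg$n_loci * len / sum(len) - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[take] <- n_chr[take] + 1L
  }
  purrr::map2_dfr(names(len), n_chr, function(ch, n) {
    if (n == 0L) return(tibble::tibble(chrom = character(), pos = integer()))
    pos <- sort(sample.int(len[[ch]], n, replace = FALSE))
    tibble::tibble(chrom = ch, pos = as.integer(pos))
  })
}

#' Per-population allele frequencies under the Balding-Nichols model
#'
#' @param cfg a [sim_config()].
#' @return list with `P` (n_pops x n_loci population frequency matrix),
#'   `ancestral` (length n_loci), and `map` (tibble `chrom`, `pos`).
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  L <- cfg$n_loci
  anc <- stats::runif(L, 0.05, 0.95)
  scale <- (1 - cfg$F) / cfg$F
  P <- matrix(0, nrow = cfg$n_pops, ncol = L)
  for (k in seq_len(cfg$n_pops)) {
    P[k, ] <- stats::rbeta(L, anc * scale, (1 - anc) * scale)
  }
  list(P = P, ancestral = anc, map = map)
}

#' Push allele frequencies toward fixation around a swept site
#'
#' In the affected population only, the alt-allele frequency of each locus at
#' distance d from the focal position is moved toward 1 with weight
#' exp(-d / strength); other populations are untouched. This emulates the
#' local hitchhiking footprint of a completed sweep at the frequency level,
#' before genotypes are drawn.
#'
#' @param freqs result of [simulate_frequencies()].
#' @param pop affected population index.
#' @param chrom,pos focal chromosome and position (bp).
#' @param strength length scale in bp of the exponential weight.
#' @return `freqs` with modified `P` and a `sweep` attribute recording the
#'   injection.
#' @export
inject_sweep <- function(freqs, pop, chrom, pos, strength) {
  map <- freqs$map
  if (!chrom %in% map$chrom) stop("sweep chromosome has no loci")
  stopifnot(pop >= 1, pop <= nrow(freqs$P))
  on_chr <- which(map$chrom == chrom)
  d <- abs(map$pos[on_chr] - pos)
  w <- exp(-d / strength)
  p <- freqs$P[pop, on_chr]
  freqs$P[pop, on_chr] <- p * (1 - w) + 1 * w
  freqs$sweep <- list(pop = pop, chrom = chrom, pos = pos, strength = strength)
  freqs
}

#' Simulate a diploid genotype panel with known structure
#'
#' @param cfg a [sim_config()].
#' @param freqs optional result of [simulate_frequencies()]; generated from
#'   `cfg` when omitted (with the sweep from `cfg$sweep` injected).
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (list with the
#'   admixture matrix `Q`, population frequencies `P`, population of origin,
#'   `F`, and the sweep description or `NULL`).
#' @export
simulate_genotypes <- function(cfg, freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(freqs)) {
    freqs <- simulate_frequencies(cfg)
    if (!is.null(cfg$sweep)) {
      freqs <- inject_sweep(freqs, cfg$sweep$pop, cfg$sweep$chrom,
                            cfg$sweep$pos, cfg$sweep$strength)
    }
  }
  set.seed(cfg$seed + 1L)
  K <- cfg$n_pops
  n <- sum(cfg$n_per_pop)
  L <- cfg$n_loci
  pop_of <- rep(seq_len(K), cfg$n_per_pop)
  # Dirichlet(alpha) with the home population favoured: individual i from
  # population k gets alpha boosted on component k so that small alpha means
  # near-pure ancestry in the home population.
  Q <- matrix(0, n, K)
  for (i in seq_len(n)) {
    a <- rep(cfg$admix_alpha, K)
    a[pop_of[i]] <- a[pop_of[i]] + 1
    g <- stats::rgamma(K, shape = a)
    Q[i, ] <- g / sum(g)
  }
  theta <- Q %*% freqs$P                 # n x L mixed frequencies
  dos <- matrix(stats::rbinom(n * L, 2L, as.vector(theta)), n, L)
  depth <- matrix(stats::rnbinom(n * L, size = cfg$depth_size,
                                 mu = cfg$depth_mean), n, L)
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    dos[miss] <- NA_integer_
    depth[miss] <- 0L
  }
  qual <- round(pmax(1, stats::rnorm(L, cfg$qual_mean, cfg$qual_mean / 6)), 1)
  sites <- freqs$map |>
    dplyr::mutate(
      ref = "A", alt = "C", qual = qual,
      is_indel = FALSE, is_multiallelic = FALSE, is_snp = TRUE
    )
  samples <- tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    species = paste0("pop", pop_of)
  )
  gm <- genotype_matrix(dos, sites, samples, depth = depth)
  truth <- list(Q = Q, P = freqs$P, pop = pop_of, F = cfg$F,
                sweep = freqs$sweep %||% NULL)
  list(gm = gm, truth = truth)
}

#' Simulate a complete panel in one call
#'
#' Convenience wrapper: frequencies, optional sweep injection, genotype draw.
#'
#' @inheritParams simulate_genotypes
#' @return As [simulate_genotypes()].
#' @export
sim_panel <- function(cfg) simulate_genotypes(cfg)

#' Write a genotype panel as a VCF 4.2 fixture
#'
#' Emits one record per locus with QUAL, `GT:DP` genotypes and `./.` for
#' missing calls. When `cfg$contaminant_fraction > 0`, indel and multiallelic
#' records are interleaved at seeded random positions so the written file
#' exercises every step of the filter cascade; contaminant genotypes are
#' homozygous reference.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg the [sim_config()] that produced it (for the contaminant rate,
#'   map and seed).
#' @param path output file path.
#' @return `path`, invisibly. The number of SNP and contaminant records is
#'   attached as attributes `n_snp` and `n_contaminant`.
#' @export
write_fixture_vcf <- function(gm, cfg, path) {
  n <- nrow(gm$dosage)
  sites <- gm$sites
  gt <- matrix("./.", n, ncol(gm$dosage))
  gt[which(gm$dosage == 0L)] <- "0/0"
  gt[which(gm$dosage == 1L)] <- "0/1"
  gt[which(gm$dosage == 2L)] <- "1/1"
  dp <- gm$depth
  if (is.null(dp)) dp <- matrix(30L, n, ncol(gm$dosage))
  body <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    qual = sites$qual,
    geno = apply(matrix(paste0(gt, ":", dp), n), 2, paste, collapse = "\t")
  )
  f <- cfg$contaminant_fraction
  n_cont <- if (f > 0) round(nrow(body) * f / (1 - f)) else 0L
  if (n_cont > 0) {
    set.seed(cfg$seed + 2L)
    chroms <- sample(names(cfg$chrom_lengths), n_cont, replace = TRUE)
    cont <- tibble::tibble(
      chrom = chroms,
      pos = as.integer(purrr::map_dbl(chroms, ~ sample.int(cfg$chrom_lengths[[.x]], 1))),
      ref = ifelse(seq_len(n_cont) %% 2 == 0, "AT", "A"),
      alt = ifelse(seq_len(n_cont) %% 2 == 0, "A", "C,T"),
      qual = cfg$qual_mean,
      geno = paste(rep("0/0:30", n), collapse = "\t")
    )
    body <- dplyr::bind_rows(body, cont) |>
      dplyr::arrange(factor(chrom, levels = names(cfg$chrom_lengths)), pos) |>
      dplyr::distinct(chrom, pos, .keep_all = TRUE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=spinpop_simulator",
    paste0("##contig=<ID=", names(cfg$chrom_lengths),
           ",length=", format(cfg$chrom_lengths, scientific = FALSE, trim = TRUE), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$id), collapse = "\t")
  )
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP\t%s",
                 body$chrom, body$pos, body$ref, body$alt,
                 format(body$qual, trim = TRUE), body$geno)
  writeLines(c(hdr, rec), path)
  n_snp <- sum(!grepl(",", body$alt) & nchar(body$ref) == 1 &
                 nchar(body$alt) == 1)
  invisible(structure(path, n_snp = n_snp, n_contaminant = nrow(body) - n_snp))
}

#' Write the simulation truth record as a TSV sidecar
#'
#' One row per sample with its admixture proportions, plus commented header
#' lines recording any injected sweep.
#'
#' @param truth the `truth` element of [simulate_genotypes()].
#' @param gm the matching [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, gm, path) {
  K <- ncol(truth$Q)
  hdr <- if (!is.null(truth$sweep)) {
    sprintf("# sweep\tchrom=%s\tpos=%d\tstrength=%g\tpop=%d",
            truth$sweep$chrom, truth$sweep$pos, truth$sweep$strength,
            truth$sweep$pop)
  } else "# sweep\tnone"
  tab <- tibble::as_tibble(truth$Q, .name_repair = ~ paste0("q", seq_len(K))) |>
    dplyr::mutate(sample = gm$samples$id, pop = truth$pop, .before = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}
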