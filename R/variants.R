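#' Read a VCF file into a genotype matrix
#'
#' Parses all records (SNPs, indels, multiallelic sites) via `vcfR`, recording
#' per-site status flags, and converts diploid `GT` fields to alt-allele
#' dosages. Half-calls, `./.` and genotypes carrying a second alternate allele
#' become missing. Sites are sorted by (chromosome, position).
#'
#' @param path path to a VCF 4.x file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ", conditionMessage(e))
  )
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) {              # single record comes back as vector
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- tibble::as_tibble(fix_mat)
  if (nrow(fix) == 0L) {
    ids <- colnames(vcf@gt)[-1] %||% character()
    return(genotype_matrix(
      matrix(integer(), length(ids), 0),
      tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), qual = numeric()),
      tibble::tibble(id = ids %||% "sample1")
    ))
  }
  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = ifelse(is.na(fix$ALT), ".", fix$ALT),
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  ids <- colnames(gt)
  # GT strings to dosage; anything not a clean diploid biallelic call -> NA
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  conv <- vapply(u, gt_to_dosage, integer(1))
  nondip <- u[!grepl("^\\.?[0-9]*[/|]\\.?[0-9]*$", u) & u != "."]
  if (length(nondip) > 0) {
    bad <- which(gt == nondip[1], arr.ind = TRUE)[1, ]
    stop("non-diploid genotype '", nondip[1], "' for sample ", ids[bad[2]])
  }
  dos <- matrix(conv[match(as.vector(gt), u)], nrow = nrow(gt))
  dos <- t(dos)                                    # samples x loci
  depth <- if (!is.null(dp)) {
    d <- t(dp); d[is.na(d)] <- 0L; d
  } else NULL
  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(
    dos[, ord, drop = FALSE],
    sites[ord, ],
    tibble::tibble(id = ids),
    depth = if (!is.null(depth)) depth[, ord, drop = FALSE]
  )
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_integer_)
  al <- strsplit(g, "[/|]")[[1]]
  if (length(al) != 2L) return(NA_integer_)
  if (any(al == ".")) return(NA_integer_)
  a <- suppressWarnings(as.integer(al))
  if (any(is.na(a))) return(NA_integer_)
  if (any(a > 1L)) return(NA_integer_)   # second alternate allele
  sum(a)
}

new_variant_panel <- function(gm, loci, universe, provenance) {
  structure(
    list(gm = gm, loci = as.integer(loci), universe = universe,
         provenance = provenance),
    class = "variant_panel"
  )
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d loci x %d samples after %d step%s\n",
              ncol(x$gm$dosage), nrow(x$gm$dosage), nrow(x$provenance),
              if (nrow(x$provenance) == 1L) "" else "s"))
  print(x$provenance, n = Inf)
  invisible(x)
}

#' @rdname tidy.variant_panel
#' @export
tidy.variant_panel <- function(x, ...) x$provenance

as_gm <- function(x) {
  if (inherits(x, "variant_panel")) x$gm
  else if (inherits(x, "genotype_matrix")) x
  else stop("expected a genotype_matrix or variant_panel")
}

site_keys <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

prov_row <- function(step, params, li, lo, si, so) {
  tibble::tibble(step = step, params = params,
                 loci_in = li, loci_out = lo,
                 samples_in = si, samples_out = so)
}

#' SNP filter cascade with per-step provenance
#'
#' Applies, in order: (1) drop indels; (2) keep biallelic SNPs only;
#' (3) MAF >= `min_maf`; (4) site quality >= `min_qual`; (5) mask genotypes
#' with depth < `min_dp` to missing; (6) drop sites with more than
#' `max_site_missing` missing; (7) drop samples with more than
#' `max_sample_missing` missing; (8) a final pass that masks depth <
#' `final_min_dp`, drops sites above `final_max_site_missing` missing and
#' re-applies MAF >= `final_min_maf` on the survivors. Each step records
#' (loci in/out, samples in/out). Set any threshold to `NULL` to disable that
#' step. MAF is always computed from non-missing alleles only.
#'
#' @param gm a [genotype_matrix()].
#' @param min_maf,min_qual,min_dp,max_site_missing,max_sample_missing,final_min_dp,final_max_site_missing,final_min_maf
#'   cascade thresholds; defaults are the GBS pipeline settings this package
#'   mirrors (MAF 0.05, QUAL 20, depth 10 then 15, 20% missingness).
#' @return A `variant_panel`: the filtered (and depth-masked) genotype matrix
#'   plus a provenance tibble; never errors on a fully filtered panel.
#' @export
filter_cascade <- function(gm,
                           min_maf = 0.05, min_qual = 20, min_dp = 10,
                           max_site_missing = 0.2, max_sample_missing = 0.2,
                           final_min_dp = 15, final_max_site_missing = 0.2,
                           final_min_maf = 0.05) {
  gm <- as_gm(gm)
  if (ncol(gm$dosage) == 0L) stop("empty genotype matrix")
  universe <- gm$sites[c("chrom", "pos", "ref", "alt")]
  cur <- gm
  keep <- seq_len(ncol(gm$dosage))
  prov <- prov_row("input", "", NA_integer_, ncol(gm$dosage),
                   NA_integer_, nrow(gm$dosage))

  drop_loci <- function(ok, step, params) {
    li <- ncol(cur$dosage); si <- nrow(cur$dosage)
    keep <<- keep[ok]
    cur <<- gm_subset(cur, loci = which(ok))
    prov <<- dplyr::bind_rows(prov, prov_row(step, params, li, ncol(cur$dosage), si, si))
  }

  drop_loci(!cur$sites$is_indel, "remove_indels", "")
  drop_loci(cur$sites$is_snp & !cur$sites$is_multiallelic, "biallelic_only", "")
  if (!is.null(min_maf)) {
    m <- maf(cur)
    drop_loci(!is.na(m) & m >= min_maf, "min_maf", sprintf("maf>=%.3g", min_maf))
  }
  if (!is.null(min_qual)) {
    q <- cur$sites$qual
    drop_loci(is.na(q) | q >= min_qual, "min_qual", sprintf("qual>=%.3g", min_qual))
  }
  if (!is.null(min_dp) && !is.null(cur$depth)) {
    li <- ncol(cur$dosage); si <- nrow(cur$dosage)
    mask <- cur$depth < min_dp
    cur$dosage[mask] <- NA_integer_
    prov <- dplyr::bind_rows(prov, prov_row("mask_low_depth",
      sprintf("dp>=%g", min_dp), li, li, si, si))
  }
  if (!is.null(max_site_missing)) {
    fr <- colMeans(is.na(cur$dosage))
    drop_loci(fr <= max_site_missing, "max_site_missing",
              sprintf("missing<=%.3g", max_site_missing))
  }
  if (!is.null(max_sample_missing)) {
    li <- ncol(cur$dosage); si <- nrow(cur$dosage)
    fr <- rowMeans(is.na(cur$dosage))
    ok <- fr <= max_sample_missing
    cur <- gm_subset(cur, samples = which(ok))
    prov <- dplyr::bind_rows(prov, prov_row("max_sample_missing",
      sprintf("missing<=%.3g", max_sample_missing), li, li, si, nrow(cur$dosage)))
  }
  # final pass
  if (!is.null(final_min_dp) && !is.null(cur$depth)) {
    li <- ncol(cur$dosage); si <- nrow(cur$dosage)
    mask <- cur$depth < final_min_dp
    cur$dosage[mask] <- NA_integer_
    prov <- dplyr::bind_rows(prov, prov_row("final_mask_low_depth",
      sprintf("dp>=%g", final_min_dp), li, li, si, si))
  }
  if (!is.null(final_max_site_missing)) {
    fr <- colMeans(is.na(cur$dosage))
    drop_loci(fr <= final_max_site_missing, "final_max_site_missing",
              sprintf("missing<=%.3g", final_max_site_missing))
  }
  if (!is.null(final_min_maf)) {
    m <- maf(cur)
    drop_loci(!is.na(m) & m >= final_min_maf, "final_min_maf",
              sprintf("maf>=%.3g", final_min_maf))
  }
  new_variant_panel(cur, keep, universe, prov)
}

pairwise_r2_matrix <- function(d) {
  suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
}

#' Windowed greedy LD pruning
#'
#' Within each sliding window of `window_snps` SNPs (stepped by `step` SNPs,
#' per chromosome), while any pair has genotypic r^2 above `r2_max`, one SNP
#' of the worst pair is removed: the lower-MAF SNP, with ties broken by the
#' later position. The surviving set has no within-window pair exceeding the
#' threshold. Mirrors PLINK `--indep-pairwise 50 5 0.2`.
#'
#' @param panel a `variant_panel` (or [genotype_matrix()]).
#' @param window_snps,step,r2_max pruning parameters.
#' @return A `variant_panel` with the pruning step appended to provenance.
#' @export
ld_prune <- function(panel, window_snps = 50, step = 5, r2_max = 0.2) {
  gm <- as_gm(panel)
  L <- ncol(gm$dosage)
  if (L == 0L) stop("empty panel")
  m <- maf(gm)
  removed <- rep(FALSE, L)
  if (r2_max < 1) {
    for (ch in unique(gm$sites$chrom)) {
      idx <- which(gm$sites$chrom == ch)
      if (length(idx) < 2L) next
      starts <- seq(1L, max(1L, length(idx) - 1L), by = step)
      for (s in starts) {
        win <- idx[s:min(s + window_snps - 1L, length(idx))]
        win <- win[!removed[win]]
        while (length(win) >= 2L) {
          r2 <- pairwise_r2_matrix(gm$dosage[, win, drop = FALSE])
          diag(r2) <- 0
          r2[is.na(r2)] <- 0
          if (max(r2) <= r2_max) break
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          a <- win[worst[1]]; b <- win[worst[2]]
          drop <- if (isTRUE(m[a] < m[b])) a
                  else if (isTRUE(m[b] < m[a])) b
                  else if (gm$sites$pos[a] > gm$sites$pos[b]) a else b
          removed[drop] <- TRUE
          win <- win[win != drop]
        }
      }
    }
  }
  ok <- which(!removed)
  out <- if (inherits(panel, "variant_panel")) panel else {
    new_variant_panel(gm, seq_len(L), gm$sites[c("chrom", "pos", "ref", "alt")],
                      prov_row("input", "", NA_integer_, L, NA_integer_,
                               nrow(gm$dosage)))
  }
  out$provenance <- dplyr::bind_rows(out$provenance, prov_row(
    "ld_prune", sprintf("window=%d,step=%d,r2<=%.3g", window_snps, step, r2_max),
    L, length(ok), nrow(gm$dosage), nrow(gm$dosage)))
  out$loci <- out$loci[ok]
  out$gm <- gm_subset(gm, loci = ok)
  out
}

#' Intersect two variant panels on shared sites
#'
#' Intersection is by (chromosome, position, ref, alt). The panels must have
#' been derived from the same site universe. When the originating
#' [genotype_matrix()] is supplied, the common panel is re-genotyped from it
#' across the union of the two panels' surviving samples, mirroring a
#' per-species filter-then-intersect workflow.
#'
#' @param panel_a,panel_b `variant_panel`s over the same universe.
#' @param gm optional originating [genotype_matrix()].
#' @return A `variant_panel` for the shared loci, provenance appended.
#' @export
common_snps <- function(panel_a, panel_b, gm = NULL) {
  stopifnot(inherits(panel_a, "variant_panel"), inherits(panel_b, "variant_panel"))
  if (!identical(panel_a$universe, panel_b$universe)) {
    stop("panels reference different site universes")
  }
  ka <- site_keys(panel_a$gm$sites)
  kb <- site_keys(panel_b$gm$sites)
  shared <- intersect(ka, kb)
  loci <- panel_a$loci[ka %in% shared]
  prov <- dplyr::bind_rows(panel_a$provenance, prov_row(
    "common_snps", sprintf("with panel of %d loci", length(kb)),
    length(ka), length(loci), nrow(panel_a$gm$dosage), nrow(panel_a$gm$dosage)))
  if (!is.null(gm)) {
    ids <- union(panel_a$gm$samples$id, panel_b$gm$samples$id)
    out_gm <- gm_subset(gm, loci = loci, samples = which(gm$samples$id %in% ids))
    prov$samples_out[nrow(prov)] <- nrow(out_gm$dosage)
  } else {
    out_gm <- gm_subset(panel_a$gm, loci = which(ka %in% shared))
  }
  new_variant_panel(out_gm, loci, panel_a$universe, prov)
}

#' SNP density in fixed physical bins
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param bin_bp bin width in bp; bins are half-open `[k*bin, (k+1)*bin)`.
#' @return tibble with `chrom`, `bin_start`, `bin_end`, `n_snps`; only
#'   occupied bins are listed, so per-chromosome totals equal panel counts.
#' @export
snp_density <- function(panel, bin_bp = 1e6) {
  gm <- as_gm(panel)
  if (ncol(gm$dosage) == 0L) stop("empty panel")
  gm$sites |>
    dplyr::mutate(bin_start = (.data$pos %/% bin_bp) * bin_bp) |>
    dplyr::count(.data$chrom, .data$bin_start, name = "n_snps") |>
    dplyr::mutate(bin_end = .data$bin_start + bin_bp, .after = "bin_start")
}
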