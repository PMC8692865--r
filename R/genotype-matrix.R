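#' Diploid genotype matrix with site and sample metadata
#'
#' The central exchange object of the pipeline: a samples x loci matrix of
#' alt-allele dosages (0, 1, 2 or `NA` for missing), a `sites` tibble with one
#' row per locus, a `samples` tibble with one row per individual, and an
#' optional matching matrix of per-genotype read depths.
#'
#' @param dosage integer matrix, samples x loci, values in `{0, 1, 2, NA}`.
#' @param sites tibble with columns `chrom`, `pos` (1-based bp), `ref`, `alt`
#'   (comma-separated for multiallelic records), `qual`, and logical flags
#'   `is_indel`, `is_multiallelic`, `is_snp` (biallelic single-nucleotide).
#' @param samples tibble with at least a character column `id`; optional
#'   `species`, `lat`, `lon`, `alt_m`.
#' @param depth optional non-negative integer matrix, same shape as `dosage`.
#'
#' @details Positions must be strictly increasing within each chromosome.
#'   Dosages other than 0/1/2/NA are rejected.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, samples, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  stopifnot(nrow(dosage) == nrow(samples), ncol(dosage) == nrow(sites))
  if (nrow(samples) < 1L) stop("need at least one sample")
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad) > 0L) stop("dosages must be 0, 1, 2 or NA")
  for (fl in c("is_indel", "is_multiallelic", "is_snp")) {
    if (is.null(sites[[fl]])) sites[[fl]] <- default_site_flag(fl, sites)
  }
  if (is.null(sites$qual)) sites$qual <- NA_real_
  check_positions(sites)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    stopifnot(all(dim(depth) == dim(dosage)))
  }
  rownames(dosage) <- samples$id
  structure(
    list(dosage = dosage, sites = sites, samples = samples, depth = depth),
    class = "genotype_matrix"
  )
}

default_site_flag <- function(fl, sites) {
  alt_split <- strsplit(as.character(sites$alt %||% ""), ",", fixed = TRUE)
  multi <- lengths(alt_split) > 1L
  indel <- nchar(as.character(sites$ref %||% "")) > 1L |
    purrr::map_lgl(alt_split, function(a) any(nchar(a) > 1L))
  switch(fl,
    is_indel = indel,
    is_multiallelic = multi,
    is_snp = !indel & !multi
  )
}

check_positions <- function(sites) {
  if (nrow(sites) < 2L) return(invisible(TRUE))
  ok <- sites |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ok$ok)) stop("positions must be strictly increasing within each chromosome")
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci (%d chromosome%s), %.1f%% missing\n",
    nrow(x$dosage), ncol(x$dosage),
    dplyr::n_distinct(x$sites$chrom),
    if (dplyr::n_distinct(x$sites$chrom) == 1L) "" else "s",
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by loci and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param loci integer or logical index into loci (columns), or `NULL` for all.
#' @param samples integer or logical index into samples (rows), or `NULL`.
#' @return A `genotype_matrix` on the selected subset.
#' @export
gm_subset <- function(gm, loci = NULL, samples = NULL) {
  if (is.null(loci)) loci <- seq_len(ncol(gm$dosage))
  if (is.null(samples)) samples <- seq_len(nrow(gm$dosage))
  genotype_matrix(
    gm$dosage[samples, loci, drop = FALSE],
    gm$sites[loci, , drop = FALSE],
    gm$samples[samples, , drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[samples, loci, drop = FALSE]
  )
}

#' Alt-allele frequencies from non-missing genotypes
#'
#' @param gm a [genotype_matrix()].
#' @param loci,samples optional index restriction.
#' @return numeric vector of alt-allele frequencies (NaN where all missing).
#' @export
allele_freqs <- function(gm, loci = NULL, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Minor-allele frequencies from non-missing genotypes
#' @inheritParams allele_freqs
#' @return numeric vector of MAFs in `[0, 0.5]` (NaN where all missing).
#' @export
maf <- function(gm, loci = NULL, samples = NULL) {
  p <- allele_freqs(gm, loci = loci, samples = samples)
  pmin(p, 1 - p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a group specification against a genotype matrix
#'
#' Groups are given tidyverse-style as a data frame with columns `sample` and
#' `group` (or a named character vector `sample -> group`). Samples absent from
#' the table get `NA` group and are excluded from grouped analyses.
#'
#' @param gm a [genotype_matrix()].
#' @param groups data frame with columns `sample`, `group`, or a named vector.
#' @return character vector of group labels aligned to `gm$samples$id`.
#' @export
group_labels <- function(gm, groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    lab <- groups$group[match(gm$samples$id, groups$sample)]
  } else {
    lab <- unname(groups[gm$samples$id])
  }
  as.character(lab)
}
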