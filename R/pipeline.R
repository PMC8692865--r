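#' Pipeline run configuration
#'
#' Either a VCF on disk (`vcf`) with an explicit group table (`groups_tsv`
#' with columns `sample`, `group`, or "infer" to derive groups from the
#' admixture fit), or a [sim_config()] to generate the input. Every stage
#' parameter defaults to the pipeline's standard setting (MAF 0.05, QUAL 20,
#' depth 10 then 15, 20% missingness, LD pruning 50/5/0.2, K chosen by
#' Evanno delta-K, 75% assignment, 999 AMOVA permutations, 200-kb LD window
#' with the r^2 = 0.2 decay criterion, 50-kb/10-kb/50-SNP sweep windows with
#' top-1% region calling and a 10-kb merge gap). A single global seed
#' derives every stage seed as `seed + stage offset`.
#'
#' @param vcf path to an input VCF, or `NULL` to simulate.
#' @param sim a [sim_config()] used when `vcf` is `NULL`.
#' @param groups "infer" or a data frame / TSV path with `sample`, `group`.
#' @param out_dir output directory for stage TSVs and the report.
#' @param seed global integer seed.
#' @param filter named list overriding [filter_cascade()] thresholds.
#' @param ld_prune_params `NULL` to skip pruning, or list(window, step, r2).
#' @param k_range,n_rep,assign_tau structure-stage parameters.
#' @param n_perm AMOVA permutations.
#' @param n_boot NJ bootstrap replicates (0 skips support values).
#' @param ld_max_dist,ld_threshold LD-stage parameters.
#' @param sweep_ref,sweep_query group labels for the sweep scan (`NULL` skips
#'   the scan when fewer than two groups are available).
#' @param sweep_params named list overriding [scan_sweeps()] parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, sim = sim_config(), groups = "infer",
                       out_dir = tempfile("spinpop_run_"), seed = 1L,
                       filter = list(), ld_prune_params = list(window = 50, step = 5, r2 = 0.2),
                       k_range = 1:5, n_rep = 3, assign_tau = 0.75,
                       n_perm = 999, n_boot = 200,
                       ld_max_dist = 200e3, ld_threshold = 0.2,
                       sweep_ref = NULL, sweep_query = NULL,
                       sweep_params = list()) {
  structure(
    list(vcf = vcf, sim = sim, groups = groups, out_dir = out_dir,
         seed = as.integer(seed), filter = filter,
         ld_prune_params = ld_prune_params, k_range = k_range, n_rep = n_rep,
         assign_tau = assign_tau, n_perm = n_perm, n_boot = n_boot,
         ld_max_dist = ld_max_dist,
         ld_threshold = ld_threshold, sweep_ref = sweep_ref,
         sweep_query = sweep_query, sweep_params = sweep_params),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments
#'   (`sim` is a list of [sim_config()] arguments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Stage order follows the analysis workflow: filter cascade (with optional
#' LD pruning) -> admixture/structure (or explicit groups) -> diversity ->
#' differentiation -> LD decay -> sweep scan. Per-stage TSVs, a provenance
#' log and a plain-text report are written to `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with every stage result (`panel`, `structure`,
#'   `assignments`, `groups`, `diversity`, `differentiation`, `amova`, `ld`,
#'   `sweeps`, `report`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("spinpop run, seed=%d, %s", cfg$seed,
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # input
  if (!is.null(cfg$vcf)) {
    gm <- read_vcf(cfg$vcf)
    note("input: VCF %s (%d samples x %d records)", cfg$vcf,
         nrow(gm$dosage), ncol(gm$dosage))
  } else {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    panel_sim <- simulate_genotypes(sim)
    gm <- panel_sim$gm
    note("input: simulated panel (%d samples x %d loci, F=%.3g)",
         nrow(gm$dosage), ncol(gm$dosage), sim$F)
  }

  # filter
  panel <- do.call(filter_cascade, c(list(gm), cfg$filter))
  if (!is.null(cfg$ld_prune_params)) {
    lp <- cfg$ld_prune_params
    panel <- ld_prune(panel, window_snps = lp$window %||% 50,
                      step = lp$step %||% 5, r2_max = lp$r2 %||% 0.2)
  }
  write_tsv_file(panel$provenance, file.path(cfg$out_dir, "filter_provenance.tsv"))
  write_tsv_file(panel$gm$sites[c("chrom", "pos", "ref", "alt")],
                 file.path(cfg$out_dir, "panel_sites.tsv"))
  note("filter: %d loci x %d samples retained", ncol(panel$gm$dosage),
       nrow(panel$gm$dosage))

  # structure / groups
  structure_res <- NULL
  assignments <- NULL
  if (identical(cfg$groups, "infer")) {
    series <- fit_admixture_series(panel, k_range = cfg$k_range,
                                   n_rep = cfg$n_rep, seed = cfg$seed + 100L)
    dk <- evanno_deltaK(series)
    k_best <- dk$K[which.max(replace(dk$delta_k, is.na(dk$delta_k), -Inf))]
    best_row <- series |>
      dplyr::filter(.data$K == k_best) |>
      dplyr::slice_max(.data$loglik, n = 1, with_ties = FALSE)
    model <- best_row$model[[1]]
    assignments <- assign_groups(model, tau = cfg$assign_tau)
    groups_tab <- assignments |>
      dplyr::filter(.data$label != "admixed") |>
      dplyr::transmute(sample = .data$sample, group = .data$label)
    structure_res <- list(series = series, delta_k = dk, K = k_best,
                          model = model)
    write_tsv_file(dk, file.path(cfg$out_dir, "evanno_delta_k.tsv"))
    write_tsv_file(assignments, file.path(cfg$out_dir, "assignments.tsv"))
    note("structure: Evanno delta-K selected K=%d; %d samples assigned, %d admixed",
         k_best, nrow(groups_tab), sum(assignments$label == "admixed"))
  } else {
    groups_tab <- if (is.character(cfg$groups)) {
      utils::read.delim(cfg$groups, stringsAsFactors = FALSE)
    } else {
      as.data.frame(cfg$groups)
    }
    note("groups: explicit table with %d samples", nrow(groups_tab))
  }
  write_tsv_file(groups_tab, file.path(cfg$out_dir, "groups.tsv"))

  # multivariate views of the same structure
  pca <- pca_genotypes(panel)
  write_tsv_file(pca$scores, file.path(cfg$out_dir, "pca_coords.tsv"))
  tree <- nj_tree(panel, n_boot = cfg$n_boot %||% 0, seed = cfg$seed + 400L)
  writeLines(tree$newick, file.path(cfg$out_dir, "nj_tree.nwk"))

  # diversity
  div <- group_summary(panel, groups_tab)
  pis <- pi_summary(panel, groups_tab)
  locus_div <- locus_diversity(panel)
  write_tsv_file(div, file.path(cfg$out_dir, "diversity_groups.tsv"))
  write_tsv_file(locus_div, file.path(cfg$out_dir, "diversity_loci.tsv"))
  write_tsv_file(pis, file.path(cfg$out_dir, "pi_groups.tsv"))

  # differentiation
  am <- amova(panel, groups_tab, n_perm = cfg$n_perm, seed = cfg$seed + 200L)
  diffs <- differentiation_summary(panel, groups_tab)
  write_tsv_file(am$table, file.path(cfg$out_dir, "amova.tsv"))
  write_tsv_file(diffs, file.path(cfg$out_dir, "differentiation_pairs.tsv"))
  note("amova: PhiPT=%.4f p=%.4g", am$phi_pt, am$p_value)

  # LD decay per group
  ld <- purrr::map_dfr(unique(groups_tab$group), function(g) {
    pr <- pairwise_r2(panel, groups_tab, group_name = g,
                      max_dist = cfg$ld_max_dist)
    if (nrow(pr) == 0L) {
      return(tibble::tibble(group = g, decay_bp = NA_real_, n_pairs = 0L))
    }
    cv <- decay_curve(pr)
    tibble::tibble(group = g,
                   decay_bp = as.numeric(decay_distance(cv, cfg$ld_threshold)),
                   n_pairs = nrow(pr))
  })
  write_tsv_file(ld, file.path(cfg$out_dir, "ld_decay.tsv"))

  # sweep scan
  sweeps_res <- NULL
  gs <- unique(groups_tab$group)
  ref_g <- cfg$sweep_ref %||% gs[1]
  qry_g <- cfg$sweep_query %||% gs[2]
  if (!is.na(qry_g) && length(gs) >= 2L) {
    sw_args <- c(list(panel, groups_tab, ref_g, qry_g,
                      seed = cfg$seed + 300L), cfg$sweep_params)
    sweeps_res <- tryCatch(do.call(scan_sweeps, sw_args), error = function(e) {
      note("sweeps: skipped (%s)", conditionMessage(e))
      NULL
    })
    if (!is.null(sweeps_res)) {
      write_tsv_file(dplyr::select(sweeps_res$windows, -"snp_idx"),
                     file.path(cfg$out_dir, "sweep_windows.tsv"))
      write_tsv_file(sweeps_res$regions,
                     file.path(cfg$out_dir, "sweep_regions.tsv"))
      note("sweeps: %d regions at top %.3g%%", nrow(sweeps_res$regions),
           100 * (cfg$sweep_params$top_fraction %||% 0.01))
    }
  }

  res <- list(panel = panel, structure = structure_res,
              assignments = assignments, pca = pca, tree = tree,
              groups = groups_tab,
              diversity = div, pi = pis, differentiation = diffs, amova = am,
              ld = ld, sweeps = sweeps_res)
  report <- make_report(res)
  writeLines(report, file.path(cfg$out_dir, "report.txt"))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  res$report <- report
  invisible(res)
}

#' Assemble the plain-text report from stage outputs
#'
#' Sections mirror the standard result tables: the AMOVA table (df, SS,
#' estimated variance, percent, PhiPT, Nm, p), the pairwise table (Fst, D,
#' Id, Nm), the per-group diversity table (N, Na, Ne, h, uh, I, pi), and the
#' sweep-region table (start, stop, number of SNPs, average score). All
#' numbers are re-derivable from the stage TSVs.
#'
#' @param res stage-result list from [run_pipeline()].
#' @return character vector of report lines.
#' @export
make_report <- function(res) {
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = "\t"),
      do.call(paste, c(lapply(df, function(x) {
        if (is.numeric(x)) signif(x, 6) else x
      }), sep = "\t")))
  }
  lines <- c("== spinpop report ==", "")
  lines <- c(lines, "-- Filter provenance --",
             fmt_tab(res$panel$provenance), "")
  lines <- c(lines, "-- AMOVA (df, SS, est. var., %, PhiPT, Nm, p) --",
             fmt_tab(res$amova$table),
             sprintf("PhiPT\t%.4f\tNm\t%.4g\tp\t%.4g", res$amova$phi_pt,
                     res$amova$nm, res$amova$p_value), "")
  lines <- c(lines, "-- Pairwise differentiation (Fst, D, Id, Nm) --",
             fmt_tab(res$differentiation[c("group_a", "group_b", "fst_phipt",
                                           "d", "id", "nm")]), "")
  div <- dplyr::left_join(res$diversity,
                          res$pi[c("group", "pi_mean")], by = "group")
  lines <- c(lines, "-- Group diversity (N, Na, Ne, h, uh, I, pi) --",
             fmt_tab(div), "")
  lines <- c(lines, "-- LD decay --", fmt_tab(res$ld), "")
  if (!is.null(res$sweeps) && nrow(res$sweeps$regions) > 0) {
    lines <- c(lines, "-- Sweep regions (start, stop, SNPs, avg score) --",
               fmt_tab(res$sweeps$regions))
  } else {
    lines <- c(lines, "-- Sweep regions --", "no regions at top 1%")
  }
  lines
}
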