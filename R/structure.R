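#' Maximum-likelihood admixture model fit by EM
#'
#' Fits the admixture likelihood in which each diploid dosage g_il is
#' Binomial(2, sum_k q_ik p_kl): individual admixture proportions Q (n x K)
#' and group alt-allele frequencies P (K x L) are alternated by
#' expectation-maximization until the relative log-likelihood change falls
#' below `tol`. Plain EM cycles are accelerated with a squared-extrapolation
#' (SQUAREM-style) step that falls back to the unaccelerated update whenever
#' extrapolation would decrease the likelihood, so the recorded
#' log-likelihood trace is non-decreasing. Missing dosages are skipped in the
#' likelihood. Initialization is k-means on PCA coordinates, perturbed by
#' `seed`, so restarts explore different basins.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param K number of groups (>= 1).
#' @param seed integer seed (initialization and restarts).
#' @param max_iter maximum accelerated cycles (each evaluates up to three EM
#'   updates).
#' @param tol relative log-likelihood convergence tolerance per cycle.
#' @return An `admix_model`: list with `K`, `Q` (n x K), `P` (K x L),
#'   `loglik`, `loglik_trace`, `converged`, `seed`, `sample_ids`.
#' @export
fit_admixture <- function(panel, K, seed = 1L, max_iter = 200, tol = 1e-7) {
  gm <- as_gm(panel)
  n <- nrow(gm$dosage); L <- ncol(gm$dosage)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of samples")
  G <- gm$dosage
  storage.mode(G) <- "double"
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  eps <- 1e-6
  if (K == 1L) {
    p <- colSums(G0) / pmax(2 * colSums(M), 1)
    p <- pmin(pmax(p, eps), 1 - eps)
    ll <- admix_loglik(G0, M, matrix(1, n, 1), matrix(p, 1, L))
    return(new_admix_model(K, matrix(1, n, 1), matrix(p, 1, L), ll, ll, TRUE,
                           seed, gm$samples$id))
  }
  set.seed(seed)
  pc <- admix_init_coords(G0, M)
  km <- stats::kmeans(pc + matrix(stats::rnorm(length(pc), sd = 0.05 * stats::sd(pc)),
                                  nrow(pc)), centers = K, nstart = 3)
  Q <- matrix(0.5 / (K - 1), n, K)
  Q[cbind(seq_len(n), km$cluster)] <- 0.5
  Q <- Q + matrix(stats::runif(n * K, 0, 0.05), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(0, K, L)
  for (k in seq_len(K)) {
    w <- Q[, k]
    P[k, ] <- colSums(w * G0) / pmax(colSums(2 * w * M), eps)
  }
  P <- pmin(pmax(P, eps), 1 - eps)
  step <- function(Q, P) em_step(G0, G, M, Q, P, eps)
  trace <- numeric(0)
  ll_old <- admix_loglik(G0, M, Q, P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s1 <- step(Q, P)
    s2 <- step(s1$Q, s1$P)
    # squared extrapolation on the flattened parameters, with projection back
    # into the simplex / (eps, 1-eps) box and monotone fallback
    rQ <- s1$Q - Q; rP <- s1$P - P
    vQ <- s2$Q - s1$Q - rQ; vP <- s2$P - s1$P - rP
    vnorm <- sqrt(sum(vQ^2) + sum(vP^2))
    cand <- s2
    if (vnorm > 0) {
      alpha <- -sqrt(sum(rQ^2) + sum(rP^2)) / vnorm
      alpha <- min(alpha, -1)
      Qx <- Q - 2 * alpha * rQ + alpha^2 * vQ
      Px <- P - 2 * alpha * rP + alpha^2 * vP
      Qx <- pmax(Qx, eps); Qx <- Qx / rowSums(Qx)
      Px <- pmin(pmax(Px, eps), 1 - eps)
      sx <- step(Qx, Px)   # stabilization EM step after extrapolation
      if (admix_loglik(G0, M, sx$Q, sx$P) >=
          admix_loglik(G0, M, s2$Q, s2$P)) {
        cand <- sx
      }
    }
    Q <- cand$Q; P <- cand$P
    ll <- admix_loglik(G0, M, Q, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  new_admix_model(K, Q, P, ll, trace, converged, seed, gm$samples$id)
}

em_step <- function(G0, G, M, Q, P, eps) {
  n <- nrow(Q); K <- ncol(Q)
  Theta <- Q %*% P
  Theta <- pmin(pmax(Theta, eps), 1 - eps)
  ratio_alt <- G0 / Theta            # g / theta, 0 where missing
  ratio_ref <- (2 - G) / (1 - Theta)
  ratio_ref[!M] <- 0
  Qnew <- matrix(0, n, K)
  Pnew <- P
  for (k in seq_len(K)) {
    Ak <- ratio_alt * (Q[, k] %o% P[k, ])        # expected alt copies from k
    Bk <- ratio_ref * (Q[, k] %o% (1 - P[k, ]))  # expected ref copies from k
    Qnew[, k] <- rowSums(Ak) + rowSums(Bk)
    ca <- colSums(Ak)
    Pnew[k, ] <- ca / pmax(ca + colSums(Bk), eps)
  }
  list(Q = Qnew / pmax(rowSums(Qnew), eps),
       P = pmin(pmax(Pnew, eps), 1 - eps))
}

admix_loglik <- function(G0, M, Q, P) {
  eps <- 1e-9
  Theta <- pmin(pmax(Q %*% P, eps), 1 - eps)
  G <- G0
  ll_mat <- G * log(Theta) + (2 - G) * log(1 - Theta) + log(1 + (G == 1))
  sum(ll_mat[M])
}

admix_init_coords <- function(G0, M) {
  p <- colSums(G0) / pmax(2 * colSums(M), 1)
  keep <- p > 0 & p < 1
  X <- sweep(G0[, keep, drop = FALSE], 2, 2 * p[keep])
  X[!M[, keep, drop = FALSE]] <- 0
  X <- sweep(X, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(X, nu = min(5, dim(X)), nv = 0)
  sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
}

new_admix_model <- function(K, Q, P, ll, trace, converged, seed, ids) {
  colnames(Q) <- paste0("q", seq_len(K))
  structure(
    list(K = K, Q = Q, P = P, loglik = ll, loglik_trace = trace,
         converged = converged, seed = seed, sample_ids = ids),
    class = "admix_model"
  )
}

#' @export
print.admix_model <- function(x, ...) {
  cat(sprintf("<admix_model> K = %d, logLik = %.2f, %sconverged (seed %d)\n",
              x$K, x$loglik, if (x$converged) "" else "NOT ", x$seed))
  invisible(x)
}

#' Tidy and glance methods for admixture fits
#'
#' `tidy()` returns the Q matrix in long format (sample, group, proportion);
#' `glance()` a one-row model summary.
#'
#' @param x an `admix_model`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.admix_model <- function(x, ...) {
  tibble::as_tibble(x$Q) |>
    dplyr::mutate(sample = x$sample_ids, .before = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "group", values_to = "proportion")
}

#' @rdname tidy.admix_model
#' @export
glance.admix_model <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik,
                 n_iter = length(x$loglik_trace), converged = x$converged,
                 seed = x$seed)
}

#' Fit the admixture model over a range of K with replicates
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param k_range integer vector of K values.
#' @param n_rep replicate fits per K (seeded restarts).
#' @param seed base seed; replicate r of K uses `seed + 1000*K + r`.
#' @param ... passed to [fit_admixture()].
#' @return tibble with `K`, `replicate`, `loglik`, `model` (list column).
#' @export
fit_admixture_series <- function(panel, k_range = 1:10, n_rep = 5, seed = 1L,
                                 ...) {
  grid <- tidyr::expand_grid(K = as.integer(k_range),
                             replicate = seq_len(n_rep))
  grid |>
    dplyr::mutate(model = purrr::map2(.data$K, .data$replicate, function(k, r) {
      fit_admixture(panel, k, seed = seed + 1000L * k + r, ...)
    })) |>
    dplyr::mutate(loglik = purrr::map_dbl(.data$model, "loglik"),
                  .before = "model")
}

#' Evanno delta-K from per-K replicate log-likelihoods
#'
#' delta K = mean over replicates of |L(K+1) - 2 L(K) + L(K-1)| divided by the
#' standard deviation of L(K) across replicates. Defined only for interior K
#' with the same replicate count on K-1, K, K+1. Zero replicate sd yields
#' `Inf` with a warning.
#'
#' @param logliks tibble with columns `K`, `replicate`, `loglik` (e.g. from
#'   [fit_admixture_series()]).
#' @return tibble with `K`, `mean_loglik`, `sd_loglik`, `delta_k` (`NA` at the
#'   boundary K values).
#' @export
evanno_deltaK <- function(logliks) {
  tab <- logliks |>
    dplyr::select("K", "replicate", "loglik") |>
    dplyr::arrange(.data$K, .data$replicate)
  ks <- sort(unique(tab$K))
  if (length(ks) < 3L) stop("need at least three consecutive K values")
  out <- purrr::map_dfr(ks, function(k) {
    lk <- tab$loglik[tab$K == k]
    dk <- NA_real_
    if ((k - 1) %in% ks && (k + 1) %in% ks) {
      lm1 <- tab$loglik[tab$K == k - 1]
      lp1 <- tab$loglik[tab$K == k + 1]
      second <- abs(lp1 - 2 * lk + lm1)
      s <- stats::sd(lk)
      if (s == 0) {
        warning("zero replicate sd at K = ", k, "; delta K is infinite")
        dk <- Inf
      } else {
        dk <- mean(second) / s
      }
    }
    tibble::tibble(K = k, mean_loglik = mean(lk), sd_loglik = stats::sd(lk),
                   delta_k = dk)
  })
  out
}

#' Assign samples to groups at a membership threshold
#'
#' A sample is labelled with its best group when its maximum membership is at
#' least `tau` (default 0.75), otherwise "admixed".
#'
#' @param model an `admix_model`.
#' @param tau assignment threshold in `(0, 1]`.
#' @return tibble with `sample`, `best_group`, `max_membership`, `label`.
#' @export
assign_groups <- function(model, tau = 0.75) {
  best <- max.col(model$Q, ties.method = "first")
  mx <- model$Q[cbind(seq_len(nrow(model$Q)), best)]
  tibble::tibble(
    sample = model$sample_ids,
    best_group = paste0("Q", best),
    max_membership = mx,
    label = ifelse(mx >= tau, paste0("Q", best), "admixed")
  )
}

#' PCA of a genotype panel
#'
#' Dosages are centred by twice the allele frequency and scaled by
#' sqrt(2 p (1 - p)); missing entries are imputed to zero after centring;
#' monomorphic loci are dropped. Coordinates come from the SVD of the scaled
#' matrix, with the sign convention that each component's largest-magnitude
#' loading is positive.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param n_components number of components to return.
#' @return list with `scores` (tibble: sample, PC1..), `explained` (fraction
#'   of variance per component).
#' @export
pca_genotypes <- function(panel, n_components = 10) {
  gm <- as_gm(panel)
  if (nrow(gm$dosage) < 2L) stop("need at least two samples")
  G <- gm$dosage
  storage.mode(G) <- "double"
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  X <- sweep(G[, keep, drop = FALSE], 2, 2 * p[keep])
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  k <- min(n_components, nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  # deterministic sign: the largest-magnitude sample coordinate is positive
  # (a convention on scores is invariant to locus order, unlike one on
  # loadings, where ties between loci would break it)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  list(
    scores = dplyr::bind_cols(tibble::tibble(sample = gm$samples$id),
                              tibble::as_tibble(scores)),
    explained = sv$d[seq_len(k)]^2 / sum(sv$d^2)
  )
}

#' Allele-sharing distance matrix
#'
#' d(x, y) = mean over non-missing loci of |x - y| / 2, i.e. one minus the
#' proportion of shared alleles.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @return symmetric `dist`-able matrix with sample ids as dimnames.
#' @export
allele_sharing_dist <- function(panel) {
  gm <- as_gm(panel)
  sharing_dist_from_dosage(gm$dosage, gm$samples$id)
}

sharing_dist_from_dosage <- function(d, ids) {
  storage.mode(d) <- "double"
  n <- nrow(d)
  m <- !is.na(d)
  x0 <- d; x0[!m] <- 0
  storage.mode(m) <- "double"
  # sum |x - y| over joint non-missing loci via |x - y| = x + y - 2*min(x, y),
  # and min(x, y) = sum over levels l in {1, 2} of I(x >= l) I(y >= l)
  ge1 <- (d >= 1); ge1[is.na(ge1)] <- FALSE; ge1 <- ge1 * 1
  ge2 <- (d >= 2); ge2[is.na(ge2)] <- FALSE; ge2 <- ge2 * 1
  sum_min <- (ge1 %*% t(ge1)) + (ge2 %*% t(ge2))
  sx <- x0 %*% t(m)
  n_shared <- m %*% t(m)
  tot_abs <- sx + t(sx) - 2 * sum_min
  dm <- tot_abs / (2 * pmax(n_shared, 1))
  dm[n_shared == 0] <- NA
  diag(dm) <- 0
  dimnames(dm) <- list(ids, ids)
  dm
}

#' Neighbor-joining tree with locus bootstrap support
#'
#' Saitou-Nei neighbor joining on the allele-sharing distance, with support
#' values from resampling loci with replacement: support is the fraction of
#' `n_boot` replicate trees containing each internal bipartition.
#'
#' @param panel a `variant_panel` or [genotype_matrix()].
#' @param n_boot bootstrap replicates (default 200); 0 skips support values.
#' @param seed integer seed for the resampling.
#' @return list with `tree` (an `ape::phylo` with `node.label` support
#'   fractions when bootstrapped) and `newick` (character).
#' @export
nj_tree <- function(panel, n_boot = 200, seed = 1L) {
  gm <- as_gm(panel)
  if (nrow(gm$dosage) < 3L) stop("need at least three samples")
  dm <- allele_sharing_dist(gm)
  tree <- ape::nj(stats::as.dist(dm))
  if (n_boot > 0) {
    set.seed(seed)
    n <- ncol(gm$dosage)
    boots <- purrr::map(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ape::nj(stats::as.dist(sharing_dist_from_dosage(
        gm$dosage[, idx, drop = FALSE], gm$samples$id)))
    })
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- counts / n_boot
  }
  list(tree = tree, newick = ape::write.tree(tree))
}
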