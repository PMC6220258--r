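# Study-wide significance: effective number of testing conditions from the
# cross-condition z-score correlation structure, and the alpha / (N x
# n_cond x M) threshold.

#' Gene-by-condition z-score matrix
#'
#' Converts per-gene p-values into z-scores by the inverse normal
#' (`|z| = qnorm(1 - p/2)`), signed by the burden direction when a `sign`
#' matrix is supplied. Genes absent from a condition stay `NA` and are
#' handled pairwise downstream.
#'
#' @param p_matrix genes x conditions matrix (or data.frame) of p-values.
#' @param sign_matrix optional matrix of burden directions (+/- 1).
#' @return numeric matrix of z-scores; conditions with fewer than two
#'   finite entries are dropped with a warning.
#' @export
zscore_matrix <- function(p_matrix, sign_matrix = NULL) {
  P <- as.matrix(p_matrix)
  Z <- stats::qnorm(pmax(pmin(P, 1 - 1e-16), 1e-300) / 2,
                    lower.tail = FALSE)
  if (!is.null(sign_matrix)) Z <- Z * sign(as.matrix(sign_matrix))
  ok <- colSums(is.finite(Z)) >= 2L
  if (!all(ok)) {
    warning(sum(!ok), " condition(s) with < 2 genes dropped", call. = FALSE)
    Z <- Z[, ok, drop = FALSE]
  }
  Z
}

#' Effective number of testing conditions
#'
#' Average-linkage hierarchical clustering of conditions on the distance
#' `1 - |r|` between their z-score vectors (pairwise-complete correlation),
#' cut at `1 - cluster_r`; the cluster count is the effective number of
#' conditions. An eigenvalue-based effective-tests number is attached for
#' comparison.
#'
#' @param z genes x conditions z-score matrix from [zscore_matrix()].
#' @param cluster_r absolute-correlation level defining a cluster
#'   (default 0.8).
#' @return integer cluster count with attributes `clusters` (membership),
#'   `eigen_effective` (Li-Ji style eigenvalue count) and `cor` (the
#'   absolute correlation matrix).
#' @export
effective_conditions <- function(z, cluster_r = 0.8) {
  z <- as.matrix(z)
  k <- ncol(z)
  if (k < 1L) stop("need at least one condition", call. = FALSE)
  if (k == 1L) return(structure(1L, clusters = 1L, eigen_effective = 1))
  r <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0; diag(r) <- 1
  a <- abs(r)
  d <- stats::as.dist(1 - a)
  hc <- stats::hclust(d, method = "average")
  memb <- stats::cutree(hc, h = 1 - cluster_r)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  eig_eff <- sum(as.integer(ev >= 1) + (ev - floor(ev)))
  structure(length(unique(memb)), clusters = memb,
            eigen_effective = eig_eff, cor = r)
}

#' Study-wide significance threshold
#'
#' `alpha_eff = alpha / (N x n_cond x M)` for `N` genes tested per
#' condition on average, `n_cond` effective conditions and `M` traits.
#'
#' @param N mean number of genes tested per condition.
#' @param n_cond effective number of conditions.
#' @param M number of traits.
#' @param alpha family-wise alpha (default 0.05).
#' @return list with `threshold` (full precision) and `threshold_2sf`
#'   (2 significant figures, the reporting convention).
#' @export
study_wide_threshold <- function(N, n_cond, M, alpha = 0.05) {
  vals <- c(N = N, n_cond = n_cond, M = M, alpha = alpha)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all threshold inputs must be positive", call. = FALSE)
  }
  thr <- alpha / (N * n_cond * M)
  list(threshold = thr, threshold_2sf = signif(thr, 2))
}

#' Export the multiple-testing report
#' @param z z-score matrix.
#' @param N,M see [study_wide_threshold()].
#' @param cluster_r see [effective_conditions()].
#' @param path optional JSON output path.
#' @return report list (N, n_cond_raw, n_cond_eff, M, alpha_eff).
#' @export
threshold_report <- function(z, N, M, cluster_r = 0.8, path = NULL) {
  nc <- effective_conditions(z, cluster_r)
  thr <- study_wide_threshold(N, as.integer(nc), M)
  rep <- list(N = N, n_cond_raw = ncol(z), n_cond_eff = as.integer(nc),
              n_cond_eigen = attr(nc, "eigen_effective"), M = M,
              alpha_eff = thr$threshold,
              alpha_eff_2sf = thr$threshold_2sf)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  }
  rep
}
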