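# Genetic relatedness estimation: centered GRM with self-kinship diagonal,
# LD pruning, PLINK-style method-of-moments pi-hat, and relative exclusion.

#' Compute a centered genetic relatedness matrix
#'
#' Centered, frequency-standardised GRM over common variants:
#' `K = (1/m) * sum_j (x_j - 2 p_j)(x_j - 2 p_j)' / (2 p_j (1 - p_j))`,
#' with missing dosages mean-imputed per variant. The diagonal is replaced
#' by a self-kinship estimate `1 + F_hat`, with `F_hat` the method-of-moments
#' inbreeding coefficient from observed versus expected homozygosity. The
#' matrix is on the "2 x kinship" scale: duplicate pairs sit near 1,
#' parent-offspring near 0.5, outbred diagonals near 1.
#'
#' @param cohort a `cohort`.
#' @param maf_min minimum MAF for inclusion (default 0.05).
#' @param miss_max maximum missingness (default 0.01).
#' @param pruned_indices optional LD-pruned variant index set; inclusion
#'   filters are applied within it.
#' @return object of class `kinship_matrix`: list(matrix, diagonal, method,
#'   n_variants).
#' @export
compute_grm <- function(cohort, maf_min = 0.05, miss_max = 0.01,
                        pruned_indices = NULL) {
  D <- cohort$dosages
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  idx <- pruned_indices %||% seq_len(ncol(D))
  maf <- cohort_maf(cohort)[idx]
  miss <- colMeans(is.na(D[, idx, drop = FALSE]))
  idx <- idx[!is.na(maf) & maf >= maf_min & miss < miss_max]
  if (!length(idx)) stop("no variants pass GRM filters", call. = FALSE)
  X <- D[, idx, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  # mean-impute and standardise
  Xc <- sweep(X, 2L, 2 * p)
  Xc[is.na(Xc)] <- 0
  sd_j <- sqrt(2 * p * (1 - p))
  Xs <- sweep(Xc, 2L, sd_j, "/")
  K <- tcrossprod(Xs) / length(idx)

  # self-kinship 1 + F_hat from homozygosity excess
  het_obs <- rowSums(X == 1L, na.rm = TRUE)
  nonmiss <- rowSums(!is.na(X))
  het_exp_j <- 2 * p * (1 - p)
  het_exp <- drop((!is.na(X)) %*% het_exp_j)
  Fhat <- 1 - het_obs / het_exp
  diag(K) <- 1 + Fhat
  dimnames(K) <- list(cohort$sample_ids, cohort$sample_ids)
  structure(list(matrix = K, diagonal = diag(K),
                 method = "centered GRM (2k scale), MoM self-kinship",
                 n_variants = length(idx)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("<kinship_matrix> %d samples, %d variants (%s)\n",
              nrow(x$matrix), x$n_variants, x$method))
  cat(sprintf("  diagonal mean %.3f; off-diagonal mean %.4f, max %.3f\n",
              mean(x$diagonal), mean(off), max(off)))
  invisible(x)
}

#' Greedy LD pruning
#'
#' Scans variants left to right; a variant is dropped if its squared
#' correlation with any retained variant within `window_bp` behind it
#' exceeds `r2_max`. Deterministic.
#'
#' @param cohort a `cohort`.
#' @param r2_max r-squared threshold (default 0.2).
#' @param window_bp window size in bp (default 500 kb).
#' @param candidate_idx optional variant subset to prune within (in position
#'   order).
#' @return retained variant indices.
#' @export
ld_prune <- function(cohort, r2_max = 0.2, window_bp = 5e5,
                     candidate_idx = NULL) {
  idx <- candidate_idx %||% seq_len(ncol(cohort$dosages))
  X <- cohort$dosages[, idx, drop = FALSE]
  n <- nrow(X)
  # centre/impute/scale once
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2L, mu)
  Xc[is.na(Xc)] <- 0
  ss <- sqrt(colSums(Xc^2))
  ss[ss == 0] <- Inf   # monomorphic: zero correlation with everything
  Xs <- sweep(Xc, 2L, ss, "/")
  pos <- cohort$positions_bp[idx]
  kept <- integer(0)
  lo <- 1L
  for (j in seq_along(idx)) {
    while (lo <= length(kept) && pos[kept[lo]] < pos[j] - window_bp) {
      lo <- lo + 1L
    }
    win <- if (lo <= length(kept)) kept[lo:length(kept)] else integer(0)
    drop <- FALSE
    if (length(win)) {
      r <- crossprod(Xs[, win, drop = FALSE], Xs[, j])
      drop <- any(r^2 > r2_max)
    }
    if (!drop) kept <- c(kept, j)
  }
  idx[kept]
}

#' Method-of-moments pairwise pi-hat
#'
#' PLINK-style `--genome` estimator: from the identity-by-state (IBS)
#' sharing counts of each pair and the allele frequencies, solves the
#' method-of-moments system for P(IBD=0), P(IBD=1), P(IBD=2) and reports
#' `pihat = P(IBD2) + P(IBD1)/2`. Probabilities are clamped to `[0, 1]`
#' before combining, so pihat lies in `[0, 1]` up to the estimator's noise.
#'
#' @param cohort a `cohort`.
#' @param variant_idx variant subset (typically common, LD-pruned variants).
#' @return data.frame of class `pihat_table`: id1, id2, pihat, p_ibd0,
#'   p_ibd1, p_ibd2.
#' @export
estimate_pihat <- function(cohort, variant_idx = NULL) {
  idx <- variant_idx %||% seq_len(ncol(cohort$dosages))
  X <- cohort$dosages[, idx, drop = FALSE]
  keep <- colSums(is.na(X)) == 0L
  X <- X[, keep, drop = FALSE]
  n <- nrow(X); m <- ncol(X)
  p <- colMeans(X) / 2
  q <- 1 - p
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]; p <- p[poly]; q <- q[poly]; m <- ncol(X)

  # per-variant expected IBS-class probabilities given IBD state
  e_ibs0_ibd0 <- sum(2 * p^2 * q^2)
  e_ibs1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e_ibs2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e_ibs1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e_ibs2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)

  # pairwise IBS counts via indicator cross-products
  A0 <- (X == 0L) + 0; A1 <- (X == 1L) + 0; A2 <- (X == 2L) + 0
  N0 <- tcrossprod(A0, A2); N0 <- N0 + t(N0)          # opposite homozygotes
  C11 <- tcrossprod(A1)
  C01 <- tcrossprod(A0, A1); C21 <- tcrossprod(A2, A1)
  N1 <- C01 + t(C01) + C21 + t(C21)                   # one het, one hom
  N2 <- m - N0 - N1

  ut <- which(upper.tri(N0), arr.ind = TRUE)
  P0 <- N0[ut] / e_ibs0_ibd0
  P1 <- (N1[ut] - P0 * e_ibs1_ibd0) / e_ibs1_ibd1
  P2 <- (N2[ut] - P0 * e_ibs2_ibd0 - P1 * e_ibs2_ibd1) / m
  P0c <- pmin(pmax(P0, 0), 1)
  P1c <- pmin(pmax(P1, 0), 1)
  P2c <- pmin(pmax(P2, 0), 1)
  pihat <- P2c + P1c / 2
  out <- data.frame(id1 = cohort$sample_ids[ut[, 1]],
                    id2 = cohort$sample_ids[ut[, 2]],
                    pihat = pihat, p_ibd0 = P0c, p_ibd1 = P1c, p_ibd2 = P2c,
                    stringsAsFactors = FALSE)
  class(out) <- c("pihat_table", "data.frame")
  out
}

#' Randomly exclude one member of each related pair
#'
#' While any pair exceeds the pi-hat threshold, picks an offending pair in
#' seeded random order and removes one random member. The retained set
#' contains no pair above the threshold.
#'
#' @param pihat a `pihat_table`.
#' @param threshold pi-hat threshold (default 0.2, exclusive).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param sample_ids full sample id set (defaults to ids present in the
#'   table).
#' @return character vector of retained sample ids.
#' @export
prune_related <- function(pihat, threshold = 0.2, seed = 1L,
                          sample_ids = NULL) {
  ids <- sample_ids %||% sort(unique(c(pihat$id1, pihat$id2)))
  off <- pihat[pihat$pihat > threshold, c("id1", "id2"), drop = FALSE]
  retained <- ids
  with_seed(seed, {
    while (nrow(off) > 0L) {
      k <- sample.int(nrow(off), 1L)
      victim <- sample(c(off$id1[k], off$id2[k]), 1L)
      retained <- setdiff(retained, victim)
      off <- off[off$id1 != victim & off$id2 != victim, , drop = FALSE]
    }
    retained
  })
}
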