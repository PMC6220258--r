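# Resampling-based comparison of rare-variant counts between cohorts of
# unequal size: size-matched subsamples of the larger cohort build the
# empirical distribution against which the smaller cohort's counts are
# judged, with a normal-fit tail when the observation leaves the empirical
# range.

#' Minor-allele-count spectrum of a sample subset
#'
#' For the given subsample, counts the variants whose within-subsample
#' minor allele count equals each class `1..mac_max`; variants monomorphic
#' in the subsample are excluded.
#'
#' @param cohort a `cohort`.
#' @param subset sample indices (default all).
#' @param mac_max largest MAC class reported.
#' @return named integer vector of length `mac_max` (names "1".."mac_max").
#' @export
mac_spectrum <- function(cohort, subset = NULL, mac_max = 29L) {
  subset <- subset %||% seq_along(cohort$sample_ids)
  if (!length(subset)) stop("empty sample subset", call. = FALSE)
  mac <- cohort_mac(cohort, subset)
  mac <- mac[!is.na(mac) & mac >= 1 & mac <= mac_max]
  stats::setNames(tabulate(mac, nbins = mac_max), as.character(1:mac_max))
}

#' Spectra of repeated size-matched subsamples
#'
#' Draws `n_reps` independent without-replacement subsamples of size
#' `n_small` from the cohort and tabulates each subsample's MAC spectrum.
#'
#' @param cohort the larger `cohort`.
#' @param n_small subsample size.
#' @param n_reps number of replicates.
#' @param mac_max largest MAC class.
#' @param seed integer seed.
#' @return `n_reps` x `mac_max` matrix of counts.
#' @export
resample_spectrum <- function(cohort, n_small, n_reps, mac_max = 29L,
                              seed = 1L) {
  n <- length(cohort$sample_ids)
  if (n_small > n) stop("n_small exceeds cohort size", call. = FALSE)
  with_seed(seed, {
    out <- matrix(0L, nrow = n_reps, ncol = mac_max,
                  dimnames = list(NULL, as.character(1:mac_max)))
    for (r in seq_len(n_reps)) {
      out[r, ] <- mac_spectrum(cohort, sample.int(n, n_small), mac_max)
    }
    out
  })
}

#' One-sided tail probability of an observed count against replicates
#'
#' Smoothed empirical tail `p = (#{at least as extreme} + 1) / (n_reps +
#' 1)`. When the observation falls outside the replicate range (so the
#' empirical quantile saturates), a normal distribution is fitted to the
#' replicate values and its tail probability is reported instead, tagged
#' `"normal-fit"`.
#'
#' @param observed observed count in the smaller cohort.
#' @param replicates replicate counts from the larger cohort.
#' @param side `"greater"` (observed unusually high) or `"less"`.
#' @return list(p, method) with method `"empirical"` or `"normal-fit"`.
#' @export
tail_p <- function(observed, replicates, side = c("greater", "less")) {
  side <- match.arg(side)
  nr <- length(replicates)
  if (nr < 30L) stop("need at least 30 replicates", call. = FALSE)
  extreme <- if (side == "greater") sum(replicates >= observed) else
    sum(replicates <= observed)
  outside <- observed > max(replicates) || observed < min(replicates)
  if (outside) {
    s <- stats::sd(replicates)
    if (s == 0) {
      return(list(p = 1 / (nr + 1), method = "empirical-bound"))
    }
    mu <- mean(replicates)
    p <- if (side == "greater") {
      stats::pnorm(observed, mu, s, lower.tail = FALSE)
    } else {
      stats::pnorm(observed, mu, s)
    }
    return(list(p = max(p, 1e-300), method = "normal-fit"))
  }
  list(p = (extreme + 1) / (nr + 1), method = "empirical")
}

#' Compare the rare-variant spectra of two cohorts
#'
#' Size-matches the larger cohort to the smaller by resampling and reports,
#' per MAC class, the smaller cohort's observed count, the replicate
#' median, and the one-sided tail p (empirical, or normal-fit outside the
#' empirical range).
#'
#' @param small,large two `cohort` objects (small must not exceed large).
#' @param n_reps replicates (default 500).
#' @param mac_max largest MAC class (default 29).
#' @param side one-sided direction for the comparison.
#' @param seed integer seed.
#' @return object of class `sfs_comparison`: data.frame per MAC class with
#'   `observed`, `replicate_median`, `p`, `method`.
#' @export
compare_sfs <- function(small, large, n_reps = 500L, mac_max = 29L,
                        side = "greater", seed = 1L) {
  n_small <- length(small$sample_ids)
  if (n_small > length(large$sample_ids)) {
    stop("`small` has more samples than `large`", call. = FALSE)
  }
  obs <- mac_spectrum(small, mac_max = mac_max)
  reps <- resample_spectrum(large, n_small, n_reps, mac_max, seed)
  rows <- lapply(seq_len(mac_max), function(k) {
    tp <- tail_p(obs[k], reps[, k], side)
    data.frame(mac = k, observed = obs[k],
               replicate_median = stats::median(reps[, k]),
               p = tp$p, method = tp$method)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sfs_comparison", "data.frame")
  out
}

#' MAC to MAF conversion (reporting convention)
#'
#' `maf = mac / (2 n)` rounded to `digits` significant figures, matching
#' the display convention for reported frequencies.
#'
#' @param mac minor allele count (0..2n).
#' @param n_samples diploid sample count.
#' @param digits significant figures (default 2).
#' @return MAF.
#' @export
mac_maf_bounds <- function(mac, n_samples, digits = 2L) {
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (any(mac < 0 | mac > 2 * n_samples)) {
    stop("mac out of range", call. = FALSE)
  }
  signif(mac / (2 * n_samples), digits)
}

#' Largest MAC at or below a MAF bound
#'
#' `floor(maf * 2n)`, the largest minor allele count whose frequency does
#' not exceed `maf`.
#'
#' @param maf frequency bound in `[0, 0.5]`.
#' @param n_samples diploid sample count.
#' @return integer MAC.
#' @export
maf_to_max_mac <- function(maf, n_samples) {
  if (maf < 0 || maf > 0.5) stop("maf out of range", call. = FALSE)
  as.integer(floor(maf * 2 * n_samples + 1e-9))
}
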