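# Variant-selection and weighting conditions for burden testing:
# ten combinations of region of interest, inclusion filter and weight rule.

WEIGHT_EPS <- 1e-6

#' The ten burden-testing conditions
#'
#' Each condition pairs a region of interest (`exon`, `exon50`,
#' `exon50_plus_regulatory`, `regulatory_only`) with a variant inclusion
#' filter and a weighting rule:
#' \describe{
#'   \item{LOFTEE_HC}{exonic high-confidence LoF variants, unweighted.}
#'   \item{LOFTEE_LC}{exonic LoF variants of low or high confidence,
#'     unweighted.}
#'   \item{EXON_SEVERE}{exonic variants more damaging than missense,
#'     unweighted.}
#'   \item{EXON_CADD}{all exonic variants, CADD-weighted.}
#'   \item{EXON_CADD_MEDIAN}{exonic variants with CADD at or above the
#'     genome-wide median, CADD-weighted.}
#'   \item{EXON50_CADD}{variants in exons padded by 50 bp, CADD-weighted.}
#'   \item{EXONREG_EIGEN}{padded exons plus assigned regulatory features,
#'     shifted-Eigen weights.}
#'   \item{EXONREG_EIGENPHRED}{same region, Phred-rank-transformed Eigen
#'     weights.}
#'   \item{EXONREG_EIGENPCPHRED}{same region, Phred-rank-transformed EigenPC
#'     weights.}
#'   \item{REG_EIGENPHRED}{regulatory features only, Phred-rank Eigen
#'     weights.}
#' }
#' @return data.frame with columns `id`, `region_mode`, `filter_rule`,
#'   `weight_rule`.
#' @export
burden_conditions <- function() {
  data.frame(
    id = c("LOFTEE_HC", "LOFTEE_LC", "EXON_SEVERE", "EXON_CADD",
           "EXON_CADD_MEDIAN", "EXON50_CADD", "EXONREG_EIGEN",
           "EXONREG_EIGENPHRED", "EXONREG_EIGENPCPHRED", "REG_EIGENPHRED"),
    region_mode = c("exon", "exon", "exon", "exon", "exon", "exon50",
                    "exon50_plus_regulatory", "exon50_plus_regulatory",
                    "exon50_plus_regulatory", "regulatory_only"),
    filter_rule = c("lof_hc", "lof_lc", "severe", "all", "cadd_median",
                    "all", "all", "all", "all", "all"),
    weight_rule = c("unit", "unit", "unit", "cadd", "cadd", "cadd",
                    "eigen_shift", "eigen_phred", "eigenpc_phred",
                    "eigen_phred"),
    stringsAsFactors = FALSE)
}

#' Phred-scale scores by descending rank
#'
#' Maps each score to `-10 * log10(rank / N)` where `rank` is the 1-based
#' descending rank among the `N` reference scores (ties share the mean of
#' their rank range). This transform maps any score distribution's support
#' to the strictly positive half-line, so every variant keeps a nonzero
#' weight while better scores are up-weighted. The bottom rank, which would
#' map to 0, is floored at a small positive epsilon.
#'
#' @param scores numeric vector to transform.
#' @param reference optional reference score set defining the ranks
#'   (defaults to `scores` itself).
#' @return positive weights, same length as `scores`.
#' @export
phred_scale <- function(scores, reference = NULL) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  reference <- reference %||% scores
  N <- length(reference)
  # mean descending rank: (# strictly greater) + (1 + # ties)/2
  sr <- sort(reference)
  n_le <- findInterval(scores, sr)
  n_lt <- findInterval(scores, sr, left.open = TRUE)
  rk <- (N - n_le) + (n_le - n_lt + 1) / 2
  w <- -10 * log10(rk / N)
  pmax(w, WEIGHT_EPS)
}

#' Shift Eigen scores into the positive half-line
#'
#' Adds 1 to each score; results that are not strictly positive are set to a
#' small positive epsilon (1e-6).
#' @param scores numeric vector.
#' @return positive weights.
#' @export
shift_eigen <- function(scores) {
  w <- scores + 1
  w[!(w > 0)] <- WEIGHT_EPS
  w
}

#' Exact Hardy-Weinberg mid-p value
#'
#' Exact conditional (Levene-Haldane) test on the heterozygote count given
#' the allele counts; the two-sided p sums the probabilities of all
#' heterozygote counts whose probability is at most that observed, with the
#' mid-p adjustment counting only half the probability of outcomes exactly
#' as probable as the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return mid-p value in (0, 1].
#' @export
hwe_midp <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("all-zero genotype counts", call. = FALSE)
  na <- 2L * n_aa + n_Aa     # minor-ish allele count (use as given)
  nA <- 2L * n_AA + n_Aa
  rare <- min(na, nA)
  if (rare == 0L) return(1)  # monomorphic: degenerate, single outcome
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(het = h | allele counts) from the Levene-Haldane distribution
  logp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - rare - hets) / 2 + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  if (is.na(obs)) stop("observed heterozygote count has wrong parity",
                       call. = FALSE)
  tol <- 1e-12
  sum(p[p < obs - tol]) + 0.5 * sum(p[abs(p - obs) <= tol])
}

#' Pre-test variant filter
#'
#' Keeps variants that are rare or low-frequency (MAF < `maf_max`), well
#' called (missingness < `miss_max`) and consistent with Hardy-Weinberg
#' equilibrium (exact mid-p >= `hwe_min`).
#'
#' @param cohort a `cohort`.
#' @param maf_max MAF upper bound (exclusive), default 0.05.
#' @param miss_max missingness upper bound (exclusive), default 0.01.
#' @param hwe_min HWE mid-p lower bound (inclusive), default 1e-5.
#' @return integer vector of passing variant indices.
#' @export
variant_prefilter <- function(cohort, maf_max = 0.05, miss_max = 0.01,
                              hwe_min = 1e-5) {
  D <- cohort$dosages
  maf <- cohort_maf(cohort)
  miss <- colMeans(is.na(D))
  keep <- which(!is.na(maf) & maf < maf_max & miss < miss_max & maf > 0)
  if (!length(keep)) return(integer(0))
  hp <- vapply(keep, function(j) {
    d <- D[, j]; d <- d[!is.na(d)]
    hwe_midp(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  }, 0)
  keep[hp >= hwe_min]
}

#' Assign regulatory features to genes
#'
#' A feature is assigned to a gene if it overlaps the gene's exonic hull, or
#' if it overlaps any eQTL position linked to that gene. A feature whose
#' eQTL is reported for several genes is assigned to all of them; tissue is
#' ignored.
#'
#' @param features data.frame (feature_id, start, end), 0-based half-open.
#' @param exons data.frame (gene_id, start, end) of exon intervals.
#' @param eqtl_links data.frame (pos_bp, gene_id); 1-based positions.
#' @return named list: feature_id -> character vector of gene ids (features
#'   mapping to no gene are omitted).
#' @export
assign_regulatory_to_genes <- function(features, exons, eqtl_links) {
  out <- list()
  if (is.null(features) || nrow(features) == 0L) return(out)
  hulls <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], start = min(e$start),
               end = max(e$end))
  }))
  for (k in seq_len(nrow(features))) {
    fs <- features$start[k]; fe <- features$end[k]
    genes <- hulls$gene_id[hulls$start < fe & hulls$end > fs]
    if (!is.null(eqtl_links) && nrow(eqtl_links)) {
      pos0 <- eqtl_links$pos_bp - 1L
      hit <- pos0 >= fs & pos0 < fe
      genes <- union(genes, eqtl_links$gene_id[hit])
    }
    if (length(genes)) out[[features$feature_id[k]]] <- sort(genes)
  }
  out
}

#' Build per-gene region interval sets
#'
#' For every gene, constructs the interval sets used by mask building and by
#' the selection scan's four region definitions: (1) exons, (2) exons padded
#' 50 bp on either side unioned with assigned regulatory features, (3) the
#' hull spanned by the exons, (4) the hull spanned by padded exons and
#' regulatory features. All intervals 0-based half-open.
#'
#' @param exons data.frame (gene_id, start, end).
#' @param features data.frame (feature_id, start, end).
#' @param assignment feature-to-genes mapping from
#'   [assign_regulatory_to_genes()].
#' @param pad exon padding in bp (default 50).
#' @return named list per gene: list(exons, exons50, regulatory, def1, def2,
#'   def3, def4).
#' @export
gene_regions <- function(exons, features = NULL, assignment = list(),
                         pad = 50L) {
  genes <- unique(exons$gene_id)
  feat_by_id <- if (!is.null(features) && nrow(features)) {
    stats::setNames(split(features[, c("start", "end")],
                          seq_len(nrow(features))), features$feature_id)
  } else list()
  out <- lapply(genes, function(g) {
    ex <- merge_intervals(exons[exons$gene_id == g, c("start", "end")])
    ex50 <- merge_intervals(data.frame(start = pmax(0L, ex$start - pad),
                                       end = ex$end + pad))
    fids <- names(assignment)[vapply(assignment, function(gs) g %in% gs,
                                     TRUE)]
    reg <- if (length(fids)) {
      merge_intervals(do.call(rbind, feat_by_id[fids]))
    } else data.frame(start = integer(0), end = integer(0))
    def2 <- merge_intervals(rbind(ex50, reg))
    list(gene_id = g, exons = ex, exons50 = ex50, regulatory = reg,
         def1 = ex, def2 = def2, def3 = hull_interval(ex),
         def4 = hull_interval(def2))
  })
  stats::setNames(out, genes)
}

# Variant indices (within `universe`) falling in the given region mode.
region_variant_idx <- function(cohort, region, mode, universe) {
  pos0 <- cohort$positions_bp[universe] - 1L
  ivl <- switch(mode,
    exon = region$exons,
    exon50 = region$exons50,
    exon50_plus_regulatory = merge_intervals(rbind(region$exons50,
                                                   region$regulatory)),
    regulatory_only = region$regulatory,
    stop("unknown region mode: ", mode, call. = FALSE))
  universe[in_intervals(pos0, ivl)]
}

#' Build a burden mask for one gene under one condition
#'
#' Selects, among the prefiltered variants, those inside the condition's
#' region of interest that pass its inclusion filter, and attaches the
#' condition's weights. A test requires at least two qualifying variants;
#' with fewer, a skip marker is returned.
#'
#' @param gene a single entry of [gene_regions()].
#' @param condition_id one of the ids in [burden_conditions()].
#' @param cohort a `cohort`.
#' @param annotations annotation data.frame (rows aligned with variants).
#' @param prefiltered integer indices from [variant_prefilter()].
#' @param cadd_median genome-wide median CADD; defaults to the median over
#'   all annotated variants.
#' @param phred_reference optional reference score table for Phred ranking
#'   (defaults to the cohort's annotated score distribution).
#' @param snv_only if TRUE, drop variants whose alleles are not both single
#'   bases.
#' @return an object of class `burden_mask` (gene_id, condition_id,
#'   variant_indices, weights) or class `burden_skip` with a reason.
#' @export
build_mask <- function(gene, condition_id, cohort, annotations, prefiltered,
                       cadd_median = NULL, phred_reference = NULL,
                       snv_only = FALSE) {
  conds <- burden_conditions()
  row <- conds[conds$id == condition_id, ]
  if (nrow(row) != 1L) stop("unknown condition id: ", condition_id,
                            call. = FALSE)
  universe <- prefiltered
  if (snv_only) {
    universe <- universe[nchar(cohort$ref[universe]) == 1L &
                           nchar(cohort$alt[universe]) == 1L]
  }
  idx <- region_variant_idx(cohort, gene, row$region_mode, universe)
  ann <- annotations[idx, , drop = FALSE]
  keep <- switch(row$filter_rule,
    all = rep(TRUE, length(idx)),
    lof_hc = ann$lof == "HC",
    lof_lc = ann$lof %in% c("LC", "HC"),
    severe = severity_rank(ann$consequence) >
      severity_rank("missense"),
    cadd_median = {
      med <- cadd_median %||% stats::median(annotations$cadd, na.rm = TRUE)
      !is.na(ann$cadd) & ann$cadd >= med
    },
    stop("unknown filter rule", call. = FALSE))
  idx <- idx[keep]
  if (length(idx) < 2L) {
    return(structure(list(gene_id = gene$gene_id,
                          condition_id = condition_id,
                          n_variants = length(idx),
                          reason = "fewer than 2 qualifying variants"),
                     class = "burden_skip"))
  }
  ann <- annotations[idx, , drop = FALSE]
  w <- switch(row$weight_rule,
    unit = rep(1, length(idx)),
    cadd = pmax(ann$cadd, WEIGHT_EPS),
    eigen_shift = shift_eigen(ann$eigen),
    eigen_phred = phred_scale(ann$eigen,
                              phred_reference %||% annotations$eigen),
    eigenpc_phred = phred_scale(ann$eigenpc,
                                phred_reference %||% annotations$eigenpc),
    stop("unknown weight rule", call. = FALSE))
  structure(list(gene_id = gene$gene_id, condition_id = condition_id,
                 variant_indices = idx, weights = as.numeric(w)),
            class = "burden_mask")
}

#' @export
print.burden_mask <- function(x, ...) {
  cat(sprintf("<burden_mask> %s / %s: %d variants, weights in [%.3g, %.3g]\n",
              x$gene_id, x$condition_id, length(x$variant_indices),
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' @export
print.burden_skip <- function(x, ...) {
  cat(sprintf("<burden_skip> %s / %s: %s\n", x$gene_id, x$condition_id,
              x$reason))
  invisible(x)
}

#' Export masks as a weight table
#' @param masks list of `burden_mask` objects.
#' @param cohort the cohort (for variant ids).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mask_table <- function(masks, cohort, path) {
  rows <- lapply(masks, function(mk) {
    if (inherits(mk, "burden_skip")) return(NULL)
    data.frame(gene_id = mk$gene_id, condition_id = mk$condition_id,
               variant_id = cohort$variant_ids[mk$variant_indices],
               weight = mk$weights)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
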