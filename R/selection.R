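# Haplotype-based selection scan: EHH and iHS with within-bin
# standardization, gene-level |iHS| > 2 fractions with empirical
# percentiles under four gene-region definitions, and Hudson F_ST.

#' Site filter for the selection scan
#'
#' Keeps biallelic single-base SNVs with MAF >= `maf_min`, a known
#' ancestral allele, Hardy-Weinberg mid-p >= `hwe_min` and mappability >=
#' `mapp_min`.
#'
#' @param cohort a `cohort`.
#' @param annotations annotation data.frame with `mappability`.
#' @param maf_min minimum MAF (default 0.05).
#' @param hwe_min minimum HWE mid-p (default 1e-30).
#' @param mapp_min minimum mappability (default 0.8).
#' @return integer index set of sites eligible for iHS.
#' @export
selection_site_filter <- function(cohort, annotations, maf_min = 0.05,
                                  hwe_min = 1e-30, mapp_min = 0.8) {
  m <- length(cohort$positions_bp)
  snv <- nchar(cohort$ref) == 1L & nchar(cohort$alt) == 1L
  maf <- cohort_maf(cohort)
  anc_known <- !is.na(cohort$ancestral_is_ref)
  mapp <- annotations$mappability
  cand <- which(snv & !is.na(maf) & maf >= maf_min & anc_known &
                  !is.na(mapp) & mapp >= mapp_min)
  if (!length(cand)) return(integer(0))
  hp <- vapply(cand, function(j) {
    d <- cohort$dosages[, j]; d <- d[!is.na(d)]
    hwe_midp(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  }, 0)
  cand[hp >= hwe_min]
}

#' Extended haplotype homozygosity decay curve
#'
#' `EHH(x)` is the probability that two random distinct haplotypes carrying
#' the core allele are identical over the interval from the core to `x`.
#' The curve starts at 1 at the core and is non-increasing moving away.
#'
#' @param haplotypes haplotype matrix (rows = haplotypes).
#' @param core core variant column index.
#' @param allele core allele (0 or 1).
#' @param side `"right"` or `"left"`.
#' @return data.frame (site, ehh) for sites moving outward from the core,
#'   starting with the core itself at EHH 1; `NULL` when fewer than two
#'   haplotypes carry the allele.
#' @export
ehh <- function(haplotypes, core, allele, side = c("right", "left")) {
  side <- match.arg(side)
  carriers <- which(haplotypes[, core] == allele)
  nc <- length(carriers)
  if (nc < 2L) return(NULL)
  m <- ncol(haplotypes)
  sites <- if (side == "right") {
    if (core < m) (core + 1L):m else integer(0)
  } else {
    if (core > 1L) (core - 1L):1L else integer(0)
  }
  denom <- nc * (nc - 1)
  grp <- rep(1L, nc)
  out_site <- integer(length(sites)); out_ehh <- numeric(length(sites))
  H <- haplotypes[carriers, , drop = FALSE]
  for (t in seq_along(sites)) {
    j <- sites[t]
    key <- grp * 2L + H[, j]
    grp <- match(key, unique(key))
    cnt <- tabulate(grp)
    out_site[t] <- j
    out_ehh[t] <- sum(cnt * (cnt - 1)) / denom
  }
  rbind(data.frame(site = core, ehh = 1),
        data.frame(site = out_site, ehh = out_ehh))
}

# One-sided iHH: walk outward from the core refining the haplotype
# partition, accumulating the trapezoid integral of EHH against cM, and
# stop at the first site where EHH < cutoff (segment included). hit_edge
# is TRUE when the chromosome end arrives before the cutoff.
ihh_side <- function(H, core, pos_cM, cutoff, step) {
  nc <- nrow(H)
  denom <- nc * (nc - 1)
  m <- ncol(H)
  grp <- rep(1L, nc)
  prev_ehh <- 1; prev_cm <- pos_cM[core]
  ihh <- 0
  j <- core + step
  while (j >= 1L && j <= m) {
    key <- grp * 2L + H[, j]
    grp <- match(key, unique(key))
    cnt <- tabulate(grp)
    e <- sum(cnt * (cnt - 1)) / denom
    ihh <- ihh + 0.5 * (e + prev_ehh) * abs(pos_cM[j] - prev_cm)
    if (e < cutoff) return(list(ihh = ihh, hit_edge = FALSE))
    prev_ehh <- e; prev_cm <- pos_cM[j]
    j <- j + step
  }
  list(ihh = ihh, hit_edge = TRUE)
}

# Integrate an EHH decay curve against cM distance by the trapezoid rule,
# truncating at the first site where EHH < cutoff (that segment included).
# Returns list(ihh, hit_edge).
integrate_ehh <- function(curve, pos_cM, cutoff = 0.05) {
  if (is.null(curve)) return(list(ihh = NA_real_, hit_edge = FALSE))
  x <- abs(pos_cM[curve$site] - pos_cM[curve$site[1]])
  y <- curve$ehh
  ihh <- 0; hit_edge <- TRUE
  if (length(x) > 1L) {
    for (t in 2:length(x)) {
      ihh <- ihh + 0.5 * (y[t] + y[t - 1]) * (x[t] - x[t - 1])
      if (y[t] < cutoff) { hit_edge <- FALSE; break }
    }
  }
  list(ihh = ihh, hit_edge = hit_edge)
}

#' Unstandardized integrated haplotype score at one site
#'
#' Integrates the EHH decay of the derived and ancestral core alleles
#' against genetic distance on both sides of the core (trapezoid rule,
#' truncated where EHH falls below `cutoff`), and returns
#' `log(iHH_A / iHH_D)`. Sites whose integration reaches a chromosome edge
#' before the cutoff on either allele are flagged.
#'
#' @param cohort a `cohort` (phased haplotypes, ancestral orientation).
#' @param core core variant index.
#' @param cutoff EHH truncation level (default 0.05).
#' @return list with `raw_ihs`, `ihh_d`, `ihh_a`, `dac` (derived allele
#'   count), `edge` (logical) and `defined` (FALSE when either allele has
#'   < 2 carriers or zero iHH).
#' @export
unstandardized_ihs <- function(cohort, core, cutoff = 0.05) {
  H <- cohort$haplotypes
  derived <- if (cohort$ancestral_is_ref[core]) 1L else 0L
  dac <- sum(H[, core] == derived)
  ihh_one <- function(allele) {
    carriers <- which(H[, core] == allele)
    if (length(carriers) < 2L) {
      return(list(ihh = NA_real_, edge = FALSE, undefined = TRUE))
    }
    Hc <- H[carriers, , drop = FALSE]
    r <- ihh_side(Hc, core, cohort$positions_cM, cutoff, +1L)
    l <- ihh_side(Hc, core, cohort$positions_cM, cutoff, -1L)
    list(ihh = r$ihh + l$ihh, edge = r$hit_edge || l$hit_edge,
         undefined = FALSE)
  }
  d <- ihh_one(derived)
  a <- ihh_one(1L - derived)
  defined <- !d$undefined && !a$undefined && d$ihh > 0 && a$ihh > 0
  list(raw_ihs = if (defined) log(a$ihh / d$ihh) else NA_real_,
       ihh_d = d$ihh, ihh_a = a$ihh, dac = dac,
       edge = d$edge || a$edge, defined = defined)
}

#' iHS scan over a set of sites
#'
#' @param cohort a `cohort`.
#' @param sites variant indices (typically from
#'   [selection_site_filter()]).
#' @param cutoff EHH truncation level.
#' @param drop_edge drop sites whose integration hit a chromosome edge
#'   before the cutoff (default TRUE).
#' @return data.frame (site, raw_ihs, ihh_d, ihh_a, dac, edge) restricted
#'   to defined records.
#' @export
ihs_scan <- function(cohort, sites, cutoff = 0.05, drop_edge = TRUE) {
  recs <- lapply(sites, function(j) {
    r <- unstandardized_ihs(cohort, j, cutoff)
    if (!r$defined) return(NULL)
    data.frame(site = j, raw_ihs = r$raw_ihs, ihh_d = r$ihh_d,
               ihh_a = r$ihh_a, dac = r$dac, edge = r$edge)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    return(data.frame(site = integer(0), raw_ihs = numeric(0),
                      ihh_d = numeric(0), ihh_a = numeric(0),
                      dac = integer(0), edge = logical(0)))
  }
  if (drop_edge) out <- out[!out$edge, , drop = FALSE]
  out
}

#' Standardize iHS within derived-allele-count bins
#'
#' Bins records into `n_bins` equally spaced derived-allele-count bins over
#' `[1, 2n - 1]` and z-normalises the raw iHS within each bin (mean 0, sd
#' 1). Bins with fewer than two records are merged into the nearest
#' occupied bin.
#'
#' @param records data.frame from [ihs_scan()].
#' @param n_haplotypes total haplotype count 2n.
#' @param n_bins number of bins (default 82).
#' @return `records` with added `bin` and `std_ihs` columns.
#' @export
standardize_ihs <- function(records, n_haplotypes, n_bins = 82L) {
  if (nrow(records) == 0L) stop("no iHS records", call. = FALSE)
  breaks <- seq(1, n_haplotypes - 1, length.out = n_bins + 1L)
  bin <- cut(records$dac, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  # merge undersized bins into the nearest occupied bin (by bin index)
  repeat {
    cnt <- table(bin)
    small <- as.integer(names(cnt)[cnt < 2L])
    if (!length(small)) break
    occupied <- as.integer(names(cnt)[cnt >= 2L])
    if (!length(occupied)) {
      stop("iHS standardization degenerate: no bin has 2 records",
           call. = FALSE)
    }
    b <- small[1]
    nearest <- occupied[which.min(abs(occupied - b))]
    bin[bin == b] <- nearest
  }
  std <- stats::ave(records$raw_ihs, bin,
                    FUN = function(x) (x - mean(x)) / stats::sd(x))
  records$bin <- bin
  records$std_ihs <- std
  records
}

#' Gene-level fraction of extreme iHS scores
#'
#' For each gene region (one of the four definitions), the fraction of
#' contained iHS-bearing SNVs with `|std_ihs| > threshold`. Genes
#' containing no iHS-bearing SNV are excluded.
#'
#' @param records standardized records from [standardize_ihs()].
#' @param cohort a `cohort`.
#' @param regions output of [gene_regions()].
#' @param definition region definition 1-4.
#' @param threshold extremeness bound on |std iHS| (default 2).
#' @return data.frame (gene_id, definition, n_snvs, frac_extreme).
#' @export
gene_fraction_extreme <- function(records, cohort, regions, definition = 4L,
                                  threshold = 2) {
  def_name <- paste0("def", definition)
  pos0 <- cohort$positions_bp[records$site] - 1L
  rows <- lapply(regions, function(rg) {
    inside <- in_intervals(pos0, rg[[def_name]])
    n <- sum(inside)
    if (n == 0L) return(NULL)
    data.frame(gene_id = rg$gene_id, definition = definition, n_snvs = n,
               frac_extreme = mean(abs(records$std_ihs[inside]) > threshold))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), definition = integer(0),
                      n_snvs = integer(0), frac_extreme = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Empirical percentile of a gene's statistic among all genes
#'
#' Midrank percentile: `100 * (#strictly smaller + ties/2) / total`, the
#' gene itself counting as a tie. In matched mode the comparison set is
#' restricted to genes whose iHS-bearing SNV count is within `tol` (a
#' fraction) of the target gene's count.
#'
#' @param fractions data.frame from [gene_fraction_extreme()] (columns
#'   `gene_id`, `n_snvs` and a statistic column).
#' @param gene target gene id.
#' @param matched restrict to genes of similar SNV count (default FALSE).
#' @param tol SNV-count matching tolerance (default 0.10).
#' @param stat name of the statistic column (default `"frac_extreme"`).
#' @return percentile in `[0, 100]`.
#' @export
gene_percentile <- function(fractions, gene, matched = FALSE, tol = 0.10,
                            stat = "frac_extreme") {
  i <- match(gene, fractions$gene_id)
  if (is.na(i)) stop("gene not present: ", gene, call. = FALSE)
  comp <- fractions
  if (matched) {
    n0 <- fractions$n_snvs[i]
    keep <- abs(fractions$n_snvs - n0) <= tol * n0
    comp <- fractions[keep, , drop = FALSE]
  }
  if (nrow(comp) < 2L) stop("matched comparison set is empty", call. = FALSE)
  x <- comp[[stat]]; v <- fractions[[stat]][i]
  100 * (sum(x < v) + 0.5 * sum(x == v)) / length(x)
}

#' Per-SNP Hudson F_ST components
#'
#' Numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the unbiased numerator can be
#' negative for undifferentiated SNPs.
#'
#' @param p1,p2 allele frequencies in the two populations.
#' @param n1,n2 haploid sample sizes (must be > 1).
#' @return data.frame (numerator, denominator), vectorized over SNPs.
#' @export
hudson_fst_snp <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) {
    stop("sample sizes must exceed 1", call. = FALSE)
  }
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(numerator = num, denominator = den)
}

#' Weighted mean F_ST (ratio of averages)
#'
#' Combines per-SNP Hudson components as the ratio of the average numerator
#' to the average denominator -- not the average of per-SNP ratios.
#'
#' @param components data.frame from [hudson_fst_snp()].
#' @return scalar weighted-mean F_ST; `NA` when the total denominator is
#'   zero.
#' @export
weighted_mean_fst <- function(components) {
  den <- sum(components$denominator)
  if (den <= 0) return(NA_real_)
  sum(components$numerator) / den
}

#' Gene-level weighted-mean F_ST between two cohorts
#'
#' @param cohort1,cohort2 two cohorts sharing variant columns (matched
#'   sites).
#' @param regions [gene_regions()] output.
#' @param definition region definition 1-4.
#' @param sites optional variant index subset.
#' @return data.frame (gene_id, n_snvs, fst).
#' @export
gene_fst <- function(cohort1, cohort2, regions, definition = 4L,
                     sites = NULL) {
  sites <- sites %||% seq_along(cohort1$positions_bp)
  p1 <- colMeans(cohort1$dosages[, sites, drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(cohort2$dosages[, sites, drop = FALSE], na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(cohort1$dosages[, sites, drop = FALSE]))
  n2 <- 2 * colSums(!is.na(cohort2$dosages[, sites, drop = FALSE]))
  ok <- n1 > 1 & n2 > 1 & !is.na(p1) & !is.na(p2)
  comp <- hudson_fst_snp(p1[ok], n1[ok], p2[ok], n2[ok])
  pos0 <- cohort1$positions_bp[sites][ok] - 1L
  def_name <- paste0("def", definition)
  rows <- lapply(regions, function(rg) {
    inside <- in_intervals(pos0, rg[[def_name]])
    if (!sum(inside)) return(NULL)
    data.frame(gene_id = rg$gene_id, n_snvs = sum(inside),
               fst = weighted_mean_fst(comp[inside, , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_snvs = integer(0),
                      fst = numeric(0))
  }
  rownames(out) <- NULL
  out
}
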