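# Shared fixtures (built lazily, cached per test run) and independent
# oracle implementations used to validate the package's fast paths.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_cohort <- function() {
  get_fixture("small_cohort", function() {
    simulate_haplotypes(sim_config(n_samples = 120, n_variants = 2500,
                                   chrom_length_bp = 8e6, seed = 101))
  })
}

# Construct a cohort object directly from a haplotype matrix (rows =
# haplotypes; sample i owns rows 2i-1, 2i).
make_cohort <- function(H, pos_bp = NULL, recomb_rate = 1,
                        ancestral_is_ref = NULL) {
  m <- ncol(H)
  n <- nrow(H) / 2L
  pos_bp <- pos_bp %||% seq(1000L, by = 1000L, length.out = m)
  odd <- seq(1L, 2L * n, by = 2L)
  structure(list(
    haplotypes = H,
    dosages = H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE],
    chrom = "1",
    positions_bp = pos_bp,
    positions_cM = pos_bp * recomb_rate / 1e6,
    ref = rep("A", m), alt = rep("T", m),
    ancestral_is_ref = ancestral_is_ref %||% rep(TRUE, m),
    variant_ids = sprintf("v%04d", seq_len(m)),
    sample_ids = sprintf("s%04d", seq_len(n))
  ), class = "cohort")
}

make_mask <- function(idx, weights = rep(1, length(idx)), gene = "g",
                      cond = "c") {
  structure(list(gene_id = gene, condition_id = cond,
                 variant_indices = idx, weights = weights),
            class = "burden_mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# EHH by exhaustive all-pairs haplotype identity over the interval.
oracle_ehh <- function(H, core, allele, side) {
  carriers <- which(H[, core] == allele)
  nc <- length(carriers)
  if (nc < 2L) return(NULL)
  m <- ncol(H)
  sites <- if (side == "right") {
    if (core < m) (core + 1L):m else integer(0)
  } else {
    if (core > 1L) (core - 1L):1L else integer(0)
  }
  out <- data.frame(site = core, ehh = 1)
  seg <- core
  for (j in sites) {
    seg <- c(seg, j)
    cnt <- 0L; np <- 0L
    for (a in 1:(nc - 1)) for (b in (a + 1):nc) {
      np <- np + 1L
      if (all(H[carriers[a], seg] == H[carriers[b], seg])) cnt <- cnt + 1L
    }
    out <- rbind(out, data.frame(site = j, ehh = cnt / np))
  }
  out
}

# Unstandardized iHS by brute force: full EHH curves from oracle_ehh,
# trapezoid integration against cM truncated at the first site below the
# cutoff (that segment included), summed over both sides and alleles.
oracle_ihs <- function(cohort, core, cutoff = 0.05) {
  H <- cohort$haplotypes
  cm <- cohort$positions_cM
  derived <- if (cohort$ancestral_is_ref[core]) 1L else 0L
  ihh_one <- function(allele) {
    tot <- 0; edge <- FALSE; undefined <- FALSE
    for (side in c("right", "left")) {
      curve <- oracle_ehh(H, core, allele, side)
      if (is.null(curve)) return(list(ihh = NA, edge = FALSE,
                                      undefined = TRUE))
      hit_edge <- TRUE
      if (nrow(curve) > 1L) {
        for (t in 2:nrow(curve)) {
          tot <- tot + 0.5 * (curve$ehh[t] + curve$ehh[t - 1]) *
            abs(cm[curve$site[t]] - cm[curve$site[t - 1]])
          if (curve$ehh[t] < cutoff) { hit_edge <- FALSE; break }
        }
      }
      edge <- edge || hit_edge
    }
    list(ihh = tot, edge = edge, undefined = FALSE)
  }
  d <- ihh_one(derived); a <- ihh_one(1L - derived)
  defined <- !d$undefined && !a$undefined && d$ihh > 0 && a$ihh > 0
  list(raw_ihs = if (defined) log(a$ihh / d$ihh) else NA_real_,
       ihh_d = d$ihh, ihh_a = a$ihh, edge = d$edge || a$edge,
       defined = defined)
}

# Exact HWE mid-p by direct summation of the Levene-Haldane pmf computed
# with choose() (independent of the package's lgamma route).
oracle_hwe_midp <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  rare <- min(2 * naa + nAa, 2 * nAA + nAa)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    nr_hom <- (rare - h) / 2
    nc_hom <- n - nr_hom - h
    exp(lchoose(n, nr_hom) + lchoose(n - nr_hom, h) + h * log(2) -
          lchoose(2 * n, rare))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  sum(pr[pr < obs - 1e-12]) + 0.5 * sum(pr[abs(pr - obs) <= 1e-12])
}
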