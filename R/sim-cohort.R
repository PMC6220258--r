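#' Simulation configuration for a synthetic phased cohort
#'
#' Builds and validates the configuration driving [simulate_haplotypes()].
#' The generator uses a mosaic-of-founders model: each sample haplotype is a
#' mosaic of a limited pool of founder haplotypes with recombination
#' breakpoints drawn as a Poisson process on the genetic (cM) map, emulating
#' the reduced haplotype diversity of a population isolate. Rare variation
#' comes from two layers: founder variants whose founder-allele counts follow
#' a skewed spectrum, and "private" mutations placed directly on one to three
#' sample haplotypes.
#'
#' @param n_samples number of diploid samples.
#' @param n_variants number of variant sites.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param recomb_rate recombination rate in cM per Mb (linear map). Ignored
#'   if `cM_map` is given.
#' @param cM_map optional piecewise genetic map: data.frame with columns
#'   `pos_bp`, `cM` (monotone); positions are linearly interpolated.
#' @param n_founder_haplotypes size of the founder haplotype pool (>= 2).
#' @param founder_spectrum_gamma skew of the founder allele-count spectrum;
#'   founder allele count k is drawn with probability proportional to
#'   k^(-gamma). Larger values enrich low-frequency founder variants.
#' @param private_frac fraction of variants that are private mutations
#'   (placed on 1-10 haplotypes with count probability proportional to
#'   1/k, so singletons dominate).
#' @param mosaic_generations expected number of mosaic breakpoints per Morgan;
#'   larger values give shorter founder segments.
#' @param indel_frac fraction of variants emitted as short INDELs (multi-base
#'   alternate allele); the remainder are SNVs.
#' @param ancestral_ref_prob probability that the reference allele is the
#'   ancestral allele at a site.
#' @param missing_rate per-genotype missingness rate injected into dosages.
#' @param relatedness_spec optional list of `list(type, count)` entries with
#'   type one of `"duplicate"`, `"parent_offspring"`, `"sib"`; consumed by
#'   [simulate_relatedness()].
#' @param sweep_spec optional list for [apply_sweep()]: `core_bp`,
#'   `carrier_frac`, `copy_length_bp`, and optional `mutation_rate`.
#' @param trait_spec optional list for [simulate_trait()]: `h2`,
#'   `causal_idx`, `beta`, optional `sigma_e`.
#' @param preset `"isolate"` (default) or `"cosmopolitan"`. The cosmopolitan
#'   preset uses a founder-rich pool (400 haplotypes) with a flatter founder
#'   spectrum and fewer private mutations, giving a markedly smaller share of
#'   MAF < 0.01 variants than the isolate default.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L, n_variants = 20000L,
                       chrom_length_bp = 5e7, recomb_rate = 1,
                       cM_map = NULL,
                       n_founder_haplotypes = NULL,
                       founder_spectrum_gamma = NULL,
                       private_frac = NULL,
                       mosaic_generations = 8,
                       indel_frac = 0.05,
                       ancestral_ref_prob = 0.9,
                       missing_rate = 0,
                       relatedness_spec = NULL,
                       sweep_spec = NULL,
                       trait_spec = NULL,
                       preset = c("isolate", "cosmopolitan"),
                       seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    isolate      = list(F = 40L,  gamma = 1.2, pf = 0.60),
    cosmopolitan = list(F = 400L, gamma = 0.5, pf = 0.30))
  n_founder_haplotypes <- n_founder_haplotypes %||% defaults$F
  founder_spectrum_gamma <- founder_spectrum_gamma %||% defaults$gamma
  private_frac <- private_frac %||% defaults$pf

  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", 2L),
    n_variants = check_count(n_variants, "n_variants", 2L),
    chrom_length_bp = check_count(chrom_length_bp, "chrom_length_bp", 1000L),
    recomb_rate = recomb_rate,
    cM_map = cM_map,
    n_founder_haplotypes = check_count(n_founder_haplotypes,
                                       "n_founder_haplotypes", 2L),
    founder_spectrum_gamma = founder_spectrum_gamma,
    private_frac = check_fraction(private_frac, "private_frac"),
    mosaic_generations = mosaic_generations,
    indel_frac = check_fraction(indel_frac, "indel_frac"),
    ancestral_ref_prob = check_fraction(ancestral_ref_prob,
                                        "ancestral_ref_prob"),
    missing_rate = check_fraction(missing_rate, "missing_rate"),
    relatedness_spec = relatedness_spec,
    sweep_spec = sweep_spec,
    trait_spec = trait_spec,
    preset = preset,
    seed = as.integer(seed))
  if (cfg$n_variants > cfg$chrom_length_bp) {
    stop("n_variants cannot exceed chrom_length_bp", call. = FALSE)
  }
  if (!is.null(sweep_spec)) {
    check_fraction(sweep_spec$carrier_frac, "sweep_spec$carrier_frac")
  }
  if (!is.null(trait_spec)) {
    check_fraction(trait_spec$h2, "trait_spec$h2")
  }
  if (!is.null(cM_map)) {
    stopifnot(is.data.frame(cM_map), all(c("pos_bp", "cM") %in% names(cM_map)))
    if (is.unsorted(cM_map$cM)) {
      stop("cM_map$cM must be nondecreasing", call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# bp -> cM using either a constant rate or a piecewise-linear map.
bp_to_cM <- function(pos_bp, cfg) {
  if (is.null(cfg$cM_map)) {
    pos_bp * cfg$recomb_rate / 1e6
  } else {
    stats::approx(cfg$cM_map$pos_bp, cfg$cM_map$cM, xout = pos_bp,
                  rule = 2)$y
  }
}

#' Simulate a phased synthetic cohort
#'
#' Generates phased haplotypes under the founder-mosaic model described in
#' [sim_config()], together with base-pair and interpolated cM positions,
#' ref/alt alleles, ancestral-allele orientation and genotype dosages.
#' The emitted site frequency spectrum is rare-variant enriched under the
#' isolate preset (the majority of variants have MAF < 0.01).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cohort`: list with `haplotypes` (2n x m 0/1
#'   matrix, sample i owns rows 2i-1 and 2i), `dosages` (n x m, `NA` where
#'   missing), `positions_bp`, `positions_cM`, `ref`, `alt`,
#'   `ancestral_is_ref`, `variant_ids`, `sample_ids`, `chrom`.
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples; m <- config$n_variants
    Fh <- config$n_founder_haplotypes
    pos_bp <- sort(sample.int(config$chrom_length_bp, m))
    pos_cM <- bp_to_cM(pos_bp, config)

    is_private <- stats::runif(m) < config$private_frac
    founders <- matrix(0L, nrow = Fh, ncol = m)
    fidx <- which(!is_private)
    if (length(fidx)) {
      kmax <- Fh - 1L
      pk <- (1:kmax)^(-config$founder_spectrum_gamma)
      k <- sample.int(kmax, length(fidx), replace = TRUE, prob = pk)
      for (t in seq_along(fidx)) {
        founders[sample.int(Fh, k[t]), fidx[t]] <- 1L
      }
    }

    # Mosaic construction: breakpoints as a Poisson process on the cM map.
    nh <- 2L * n
    H <- matrix(0L, nrow = nh, ncol = m)
    L_cM <- bp_to_cM(config$chrom_length_bp, config)
    rate_per_cM <- config$mosaic_generations / 100
    for (h in seq_len(nh)) {
      nb <- stats::rpois(1L, rate_per_cM * L_cM)
      if (nb > 0L) {
        bps <- sort(stats::runif(nb, 0, L_cM))
        seg_f <- sample.int(Fh, nb + 1L, replace = TRUE)
        seg <- findInterval(pos_cM, bps) + 1L
        H[h, ] <- founders[cbind(seg_f[seg], seq_len(m))]
      } else {
        H[h, ] <- founders[sample.int(Fh, 1L), ]
      }
    }

    # Private mutations: placed on 1-10 random haplotypes with a 1/k
    # (neutral-SFS-like) count distribution, dominated by singletons and
    # smoothly filling the low-MAC range below the founder-variant
    # frequencies.
    pidx <- which(is_private)
    if (length(pidx)) {
      cnt <- sample(1:10, length(pidx), replace = TRUE, prob = 1 / (1:10))
      for (t in seq_along(pidx)) {
        H[sample.int(nh, cnt[t]), pidx[t]] <- 1L
      }
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    is_indel <- stats::runif(m) < config$indel_frac
    if (any(is_indel)) {
      ins <- vapply(which(is_indel), function(j) {
        paste0(alt[j], paste(sample(bases, sample(1:2, 1L), replace = TRUE),
                             collapse = ""))
      }, "")
      alt[is_indel] <- ins
    }
    anc_ref <- stats::runif(m) < config$ancestral_ref_prob

    odd <- seq(1L, nh, by = 2L)
    D <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
    if (config$missing_rate > 0) {
      D[stats::runif(length(D)) < config$missing_rate] <- NA_integer_
    }

    cohort <- structure(list(
      haplotypes = H,
      dosages = D,
      chrom = "1",
      positions_bp = pos_bp,
      positions_cM = pos_cM,
      ref = ref,
      alt = unname(alt),
      ancestral_is_ref = anc_ref,
      variant_ids = sprintf("var%06d", seq_len(m)),
      sample_ids = sprintf("S%04d", seq_len(n))
    ), class = "cohort")
    cohort
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d variants, chrom %s, %.1f Mb\n",
              length(x$sample_ids), length(x$positions_bp), x$chrom,
              max(x$positions_bp) / 1e6))
  maf <- cohort_maf(x)
  cat(sprintf("  MAF<0.01: %.1f%%  missing dosages: %.2f%%\n",
              100 * mean(maf < 0.01, na.rm = TRUE),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Minor allele count and frequency from dosages
#'
#' Computed from genotype dosages, ignoring missing entries.
#' @param cohort a `cohort` object.
#' @param idx optional sample subset (indices) over which to count.
#' @return numeric vector per variant.
#' @export
cohort_mac <- function(cohort, idx = NULL) {
  D <- cohort$dosages
  if (!is.null(idx)) D <- D[idx, , drop = FALSE]
  ac <- colSums(D, na.rm = TRUE)
  nn <- 2 * colSums(!is.na(D))
  pmin(ac, nn - ac)
}

#' @rdname cohort_mac
#' @export
cohort_maf <- function(cohort, idx = NULL) {
  D <- cohort$dosages
  if (!is.null(idx)) D <- D[idx, , drop = FALSE]
  ac <- colSums(D, na.rm = TRUE)
  nn <- 2 * colSums(!is.na(D))
  p <- ifelse(nn > 0, ac / nn, NA_real_)
  pmin(p, 1 - p)
}

# Refresh dosages from haplotypes, preserving the missingness mask.
refresh_dosages <- function(cohort) {
  nh <- nrow(cohort$haplotypes)
  odd <- seq(1L, nh, by = 2L)
  D <- cohort$haplotypes[odd, , drop = FALSE] +
       cohort$haplotypes[odd + 1L, , drop = FALSE]
  D[is.na(cohort$dosages)] <- NA_integer_
  cohort$dosages <- D
  cohort
}

#' Impose a partial selective sweep on a cohort
#'
#' A fraction of haplotypes is designated as carriers of the derived allele
#' at a core site; within +/- `copy_length_bp` of the core their sequence is
#' replaced by a copy of a single donor haplotype (with optional sparse
#' mutations), producing the extended haplotype homozygosity a recent
#' positive sweep leaves around the selected allele.
#'
#' @param cohort a `cohort`.
#' @param sweep_spec list with `core_bp` (a position; the nearest variant is
#'   used as core), `carrier_frac` in `[0, 1]`, `copy_length_bp`, and
#'   optional `mutation_rate` (per copied allele flip probability, default 0).
#' @param seed integer seed.
#' @return the modified cohort; the chosen core variant index is recorded in
#'   `attr(, "sweep_core")`.
#' @export
apply_sweep <- function(cohort, sweep_spec, seed = 1L) {
  f <- check_fraction(sweep_spec$carrier_frac, "carrier_frac")
  core <- which.min(abs(cohort$positions_bp - sweep_spec$core_bp))
  if (length(core) != 1L) stop("core position not found", call. = FALSE)
  nh <- nrow(cohort$haplotypes)
  ncar <- round(f * nh)
  if (f > 0 && ncar < 1L) {
    stop("carrier fraction incompatible with haplotype count", call. = FALSE)
  }
  if (ncar == 0L) return(cohort)
  with_seed(seed, {
    carriers <- sample.int(nh, ncar)
    donor <- carriers[1L]
    win <- which(abs(cohort$positions_bp - cohort$positions_bp[core]) <=
                   sweep_spec$copy_length_bp)
    block <- cohort$haplotypes[donor, win]
    cohort$haplotypes[carriers, win] <-
      matrix(block, nrow = ncar, ncol = length(win), byrow = TRUE)
    mu <- sweep_spec$mutation_rate %||% 0
    if (mu > 0) {
      flip <- matrix(stats::runif(ncar * length(win)) < mu,
                     nrow = ncar)
      cohort$haplotypes[carriers, win][flip] <-
        1L - cohort$haplotypes[carriers, win][flip]
    }
    derived <- if (cohort$ancestral_is_ref[core]) 1L else 0L
    cohort$haplotypes[, core] <- 1L - derived
    cohort$haplotypes[carriers, core] <- derived
    cohort <- refresh_dosages(cohort)
    attr(cohort, "sweep_core") <- core
    cohort
  })
}

#' Inject pedigree relatedness into a cohort
#'
#' Replaces designated samples by pedigree constructions: duplicates (genome
#' copies), parent-offspring pairs (a child formed by meiosis of two existing
#' samples, one of which is the named parent) and full-sib pairs (two
#' children of the same two parents). Meioses recombine the parent's two
#' haplotypes with crossovers drawn on the cM map, and the grandparental
#' origin of every transmitted allele is recorded so identity-by-descent
#' states can be audited.
#'
#' @param cohort a `cohort`.
#' @param relatedness_spec list of `list(type, count)` with type one of
#'   `"duplicate"`, `"parent_offspring"`, `"sib"`.
#' @param seed integer seed.
#' @param genome_morgans expected crossovers per meiosis. The default (35,
#'   a human-genome-scale map length) treats the single simulated
#'   chromosome as a stand-in for a whole genome, so realized IBD sharing
#'   concentrates near its pedigree expectation as genome-wide sharing
#'   does.
#' @return list with elements `cohort` (modified), `kinship` (n x n
#'   pedigree-expected kinship matrix, self-kinship 0.5 on the diagonal),
#'   `pairs` (data.frame id1, id2, type, expected_pihat) and
#'   `transmissions` (per-child crossover origin records).
#' @export
simulate_relatedness <- function(cohort, relatedness_spec, seed = 1L,
                                 genome_morgans = 35) {
  n <- length(cohort$sample_ids)
  types <- vapply(relatedness_spec, function(s) s$type, "")
  counts <- vapply(relatedness_spec, function(s) as.integer(s$count), 1L)
  bad <- setdiff(types, c("duplicate", "parent_offspring", "sib"))
  if (length(bad)) stop("unknown pair type: ", bad[1], call. = FALSE)
  # Each pair consumes source samples and overwrites target slots taken from
  # the end of the sample list.
  n_slots <- sum(counts * ifelse(types == "sib", 2L, 1L))
  n_src <- sum(counts * 2L)
  if (n_slots + n_src > n) {
    stop("relatedness_spec requests more pairs than samples allow",
         call. = FALSE)
  }
  with_seed(seed, {
    phi <- diag(0.5, n)
    H <- cohort$haplotypes
    slot <- n            # next target slot (consumed from the end)
    src <- 1L            # next source sample (consumed from the front)
    pairs <- list(); trans <- list()
    hrows <- function(i) c(2L * i - 1L, 2L * i)
    for (k in seq_along(types)) {
      for (rep in seq_len(counts[k])) {
        if (types[k] == "duplicate") {
          a <- src; src <- src + 1L
          b <- slot; slot <- slot - 1L
          H[hrows(b), ] <- H[hrows(a), ]
          phi[b, ] <- phi[a, ]; phi[, b] <- phi[, a]
          phi[a, b] <- phi[b, a] <- 0.5; phi[b, b] <- 0.5
          pairs[[length(pairs) + 1L]] <-
            data.frame(id1 = a, id2 = b, type = "duplicate",
                       expected_pihat = 1)
        } else if (types[k] == "parent_offspring") {
          p1 <- src; p2 <- src + 1L; src <- src + 2L
          cidx <- slot; slot <- slot - 1L
          g1 <- meiosis(H[hrows(p1), , drop = FALSE], cohort$positions_cM, genome_morgans)
          g2 <- meiosis(H[hrows(p2), , drop = FALSE], cohort$positions_cM, genome_morgans)
          H[hrows(cidx)[1], ] <- g1$gamete
          H[hrows(cidx)[2], ] <- g2$gamete
          for (x in seq_len(n)) {
            if (x != cidx) phi[cidx, x] <- phi[x, cidx] <-
                0.5 * (phi[p1, x] + phi[p2, x])
          }
          phi[cidx, cidx] <- 0.5 * (1 + phi[p1, p2])
          trans[[length(trans) + 1L]] <-
            list(child = cidx, parents = c(p1, p2),
                 origin = rbind(g1$origin, g2$origin))
          pairs[[length(pairs) + 1L]] <-
            data.frame(id1 = p1, id2 = cidx, type = "parent_offspring",
                       expected_pihat = 0.5)
        } else { # sib
          p1 <- src; p2 <- src + 1L; src <- src + 2L
          c1 <- slot; c2 <- slot - 1L; slot <- slot - 2L
          for (cc in c(c1, c2)) {
            g1 <- meiosis(H[hrows(p1), , drop = FALSE], cohort$positions_cM, genome_morgans)
            g2 <- meiosis(H[hrows(p2), , drop = FALSE], cohort$positions_cM, genome_morgans)
            H[hrows(cc)[1], ] <- g1$gamete
            H[hrows(cc)[2], ] <- g2$gamete
            trans[[length(trans) + 1L]] <-
              list(child = cc, parents = c(p1, p2),
                   origin = rbind(g1$origin, g2$origin))
          }
          for (cc in c(c1, c2)) {
            for (x in seq_len(n)) {
              if (x != cc && x != c1 && x != c2) {
                phi[cc, x] <- phi[x, cc] <- 0.5 * (phi[p1, x] + phi[p2, x])
              }
            }
            phi[cc, cc] <- 0.5 * (1 + phi[p1, p2])
          }
          phi[c1, c2] <- phi[c2, c1] <- 0.25
          pairs[[length(pairs) + 1L]] <-
            data.frame(id1 = c1, id2 = c2, type = "sib",
                       expected_pihat = 0.5)
        }
      }
    }
    cohort$haplotypes <- H
    cohort <- refresh_dosages(cohort)
    rownames(phi) <- colnames(phi) <- cohort$sample_ids
    list(cohort = cohort, kinship = phi,
         pairs = do.call(rbind, pairs), transmissions = trans)
  })
}

# One meiosis: recombine a parent's two haplotypes along the cM map.
# `morgans` sets the expected crossover count; the default treats the
# single simulated chromosome as standing in for a whole genome, so
# realized IBD sharing concentrates near its pedigree expectation the way
# genome-wide sharing does.
# Returns the gamete and the parental-haplotype origin (1 or 2) per site.
meiosis <- function(parent_haps, pos_cM, morgans = 35) {
  L <- max(pos_cM)
  nx <- stats::rpois(1L, morgans %||% (L / 100))
  start <- sample(1:2, 1L)
  if (nx == 0L) {
    origin <- rep(start, length(pos_cM))
  } else {
    xp <- sort(stats::runif(nx, 0, L))
    seg <- findInterval(pos_cM, xp)
    origin <- ifelse(seg %% 2L == 0L, start, 3L - start)
  }
  gamete <- parent_haps[cbind(origin, seq_along(pos_cM))]
  list(gamete = gamete, origin = origin)
}

#' Simulate gene and regulatory feature models
#'
#' Lays out non-overlapping multi-exon genes along the chromosome, upstream
#' regulatory features (promoter/enhancer-like intervals), and an eQTL link
#' table tying some features to genes they do not overlap. All intervals are
#' 0-based half-open.
#'
#' @param chrom_length_bp chromosome length.
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param exon_mean mean exon length (bp).
#' @param intron_mean mean intron length (bp); controls the gene span.
#' @param n_exon_range inclusive range for the exon count per gene.
#' @return list with `exons` (gene_id, start, end), `features`
#'   (feature_id, start, end), `eqtl` (pos_bp, gene_id).
#' @export
simulate_gene_models <- function(chrom_length_bp, n_genes, seed = 1L,
                                 exon_mean = 200, intron_mean = 1500,
                                 n_exon_range = c(3L, 8L)) {
  with_seed(seed, {
    slot_len <- floor(chrom_length_bp / n_genes)
    exons <- list(); feats <- list(); eqtl <- list()
    fid <- 0L
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("GENE%03d", g)
      base <- (g - 1L) * slot_len + floor(0.25 * slot_len)
      ne <- sample(seq(n_exon_range[1], n_exon_range[2]), 1L)
      pos <- base
      es <- integer(ne); ee <- integer(ne)
      for (e in seq_len(ne)) {
        len <- max(30L, stats::rpois(1L, exon_mean))
        es[e] <- pos; ee[e] <- pos + len
        pos <- pos + len + max(200L, stats::rpois(1L, intron_mean))
      }
      exons[[g]] <- data.frame(gene_id = gene_id, start = es, end = ee)
      # promoter-like feature upstream of the first exon (direct overlap of
      # the gene hull is not guaranteed; some attach only via eQTL).
      if (stats::runif(1) < 0.8) {
        fid <- fid + 1L
        fs <- max(0L, es[1] - sample(200:2000, 1L))
        fe <- fs + sample(200:800, 1L)
        feats[[fid]] <- data.frame(feature_id = sprintf("FEAT%03d", fid),
                                   start = fs, end = fe)
        if (fe <= es[1] || stats::runif(1) < 0.5) {
          # link by eQTL: a position inside the feature linked to this gene
          eqtl[[length(eqtl) + 1L]] <-
            data.frame(pos_bp = sample(fs:(fe - 1L), 1L) + 1L,
                       gene_id = gene_id)
        }
      }
    }
    list(exons = do.call(rbind, exons),
         features = if (fid) do.call(rbind, feats) else
           data.frame(feature_id = character(0), start = integer(0),
                      end = integer(0)),
         eqtl = if (length(eqtl)) do.call(rbind, eqtl) else
           data.frame(pos_bp = integer(0), gene_id = character(0)))
  })
}

#' Consequence severity order
#'
#' The fixed severity ordering used throughout the package, least to most
#' damaging. "More damaging than missense" means any class strictly after
#' `missense` in this vector (splice_region and above).
#' @return character vector of consequence classes in increasing severity.
#' @export
consequence_levels <- function() {
  c("intergenic", "regulatory", "synonymous", "missense", "splice_region",
    "splice_acceptor", "splice_donor", "stop_gained", "frameshift")
}

lof_compatible_classes <- function() {
  c("splice_acceptor", "splice_donor", "stop_gained", "frameshift")
}

#' Severity rank of consequence classes
#' @param consequence character vector of classes from [consequence_levels()].
#' @return integer rank (1 = intergenic).
#' @export
severity_rank <- function(consequence) {
  match(consequence, consequence_levels())
}

#' Simulate functional annotations for a cohort
#'
#' Assigns consequence classes by position relative to gene models (exonic
#' classes sampled with fixed probabilities, regulatory within features,
#' intergenic elsewhere), draws CADD from a gamma distribution and
#' Eigen/EigenPC from normals, all with severity-dependent location shifts,
#' and marks a configurable subset of LoF-class variants as high or low
#' confidence. Distribution parameters are recorded in `attr(, "params")`.
#'
#' @param cohort a `cohort`.
#' @param gene_models output of [simulate_gene_models()] (or same shape).
#' @param seed integer seed.
#' @param hc_frac probability that a LoF-class variant is flagged HC.
#' @param lc_frac probability that a LoF-class variant is flagged LC.
#' @return data.frame with one row per variant: `variant_id`, `consequence`,
#'   `lof` (none/LC/HC), `cadd`, `eigen`, `eigenpc`, `mappability`,
#'   `regulatory` (comma-separated feature ids, "" if none).
#' @export
simulate_annotations <- function(cohort, gene_models, seed = 1L,
                                 hc_frac = 0.4, lc_frac = 0.45) {
  with_seed(seed, {
    m <- length(cohort$positions_bp)
    pos0 <- cohort$positions_bp - 1L
    in_exon <- in_intervals(pos0, gene_models$exons)
    # splice classes only make sense near exon boundaries; sampled freely
    exon_probs <- c(synonymous = 0.45, missense = 0.35, splice_region = 0.08,
                    splice_acceptor = 0.03, splice_donor = 0.03,
                    stop_gained = 0.04, frameshift = 0.02)
    cons <- rep("intergenic", m)
    if (any(in_exon)) {
      cons[in_exon] <- sample(names(exon_probs), sum(in_exon),
                              replace = TRUE, prob = exon_probs)
    }
    reg <- character(m); reg[] <- ""
    if (nrow(gene_models$features)) {
      for (k in seq_len(nrow(gene_models$features))) {
        hit <- pos0 >= gene_models$features$start[k] &
          pos0 < gene_models$features$end[k]
        reg[hit] <- ifelse(reg[hit] == "",
                           gene_models$features$feature_id[k],
                           paste(reg[hit], gene_models$features$feature_id[k],
                                 sep = ","))
      }
    }
    cons[!in_exon & reg != ""] <- "regulatory"

    params <- list(
      cadd = list(shape = 2, scale = 3,
                  shift = c(intergenic = 0, regulatory = 1, synonymous = 1,
                            missense = 4, splice_region = 5,
                            splice_acceptor = 10, splice_donor = 10,
                            stop_gained = 12, frameshift = 12)),
      eigen = list(sd = 1,
                   mean = c(intergenic = -0.5, regulatory = 0.5,
                            synonymous = 0, missense = 1, splice_region = 1.2,
                            splice_acceptor = 2.2, splice_donor = 2.2,
                            stop_gained = 2.5, frameshift = 2.5)))
    cadd <- stats::rgamma(m, shape = params$cadd$shape,
                          scale = params$cadd$scale) +
      params$cadd$shift[cons]
    eigen <- stats::rnorm(m, mean = params$eigen$mean[cons],
                          sd = params$eigen$sd)
    eigenpc <- stats::rnorm(m, mean = params$eigen$mean[cons] * 0.8,
                            sd = params$eigen$sd)
    lof <- rep("none", m)
    is_lofc <- cons %in% lof_compatible_classes()
    if (any(is_lofc)) {
      u <- stats::runif(sum(is_lofc))
      lof[is_lofc] <- ifelse(u < hc_frac, "HC",
                             ifelse(u < hc_frac + lc_frac, "LC", "none"))
    }
    mapp <- ifelse(stats::runif(m) < 0.9, 1, stats::runif(m, 0.3, 1))

    ann <- data.frame(variant_id = cohort$variant_ids,
                      consequence = cons, lof = lof,
                      cadd = unname(cadd), eigen = eigen, eigenpc = eigenpc,
                      mappability = mapp, regulatory = reg,
                      stringsAsFactors = FALSE)
    attr(ann, "params") <- params
    ann
  })
}

#' Simulate a quantitative trait with polygenic and rare-burden components
#'
#' Trait model: `y = a + sum_j beta_j * dosage_j + e` with polygenic
#' component `a ~ N(0, h2 * 2K)` (K the pedigree kinship, so `2K` has unit
#' diagonal for outbred samples) and noise `e ~ N(0, sigma_e^2)`. With the
#' default `sigma_e = sqrt(1 - h2)` the baseline (non-burden) variance is 1,
#' so causal effects `beta` are in trait-SD units.
#'
#' @param cohort a `cohort`.
#' @param true_kinship optional n x n kinship matrix (self-kinship 0.5 scale)
#'   from [simulate_relatedness()]; `NULL` means unrelated samples.
#' @param trait_spec list with `h2` in `[0,1]`, `causal_idx` (variant column
#'   indices, may be empty), `beta` (same length), optional `sigma_e`.
#' @param seed integer seed.
#' @return named numeric vector of trait values.
#' @export
simulate_trait <- function(cohort, true_kinship = NULL, trait_spec,
                           seed = 1L) {
  h2 <- check_fraction(trait_spec$h2, "h2")
  n <- length(cohort$sample_ids)
  sigma_e <- trait_spec$sigma_e %||% sqrt(1 - h2)
  causal <- trait_spec$causal_idx %||% integer(0)
  beta <- trait_spec$beta %||% numeric(0)
  if (length(causal) != length(beta)) {
    stop("causal_idx and beta must have equal length", call. = FALSE)
  }
  if (anyNA(causal) ||
      (length(causal) && any(causal < 1 | causal > ncol(cohort$dosages)))) {
    stop("causal_idx out of range", call. = FALSE)
  }
  with_seed(seed, {
    if (h2 > 0) {
      if (is.null(true_kinship)) {
        a <- sqrt(h2) * stats::rnorm(n)
      } else {
        S <- 2 * true_kinship
        R <- chol(S + diag(1e-8, n))
        a <- sqrt(h2) * drop(crossprod(R, stats::rnorm(n)))
      }
    } else a <- numeric(n)
    burden <- if (length(causal)) {
      G <- cohort$dosages[, causal, drop = FALSE]
      G[is.na(G)] <- 0
      drop(G %*% beta)
    } else 0
    y <- a + burden + stats::rnorm(n, sd = sigma_e)
    names(y) <- cohort$sample_ids
    y
  })
}
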