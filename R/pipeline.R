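# End-to-end orchestration: simulate (or load) -> masks -> kinship ->
# burden scan across conditions -> threshold -> selection scan.

#' Subset a cohort by samples
#' @param cohort a `cohort`.
#' @param idx sample indices or ids to keep.
#' @return the subset `cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  if (is.character(idx)) idx <- match(idx, cohort$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids in subset", call. = FALSE)
  hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  cohort$haplotypes <- cohort$haplotypes[hrows, , drop = FALSE]
  cohort$dosages <- cohort$dosages[idx, , drop = FALSE]
  cohort$sample_ids <- cohort$sample_ids[idx]
  cohort
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}

validate_run_config <- function(config) {
  if (is.null(config$simulation) && is.null(config$inputs)) {
    stop("config must contain either a `simulation` block or `inputs` paths",
         call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs)) {
      if (!file.exists(f)) {
        stop("input file does not exist: ", f, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# Materialise cohort + annotations + gene models + traits from a config.
build_stage <- function(config) {
  seed <- config$seed %||% 1L
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    cfg_args <- sim[setdiff(names(sim),
                            c("n_genes", "trait", "sweep", "relatedness",
                              "exon_mean", "intron_mean", "n_exon_range"))]
    cfg_args$seed <- derive_seed(seed, "haplotypes")
    cfg <- do.call(sim_config, cfg_args)
    cohort <- simulate_haplotypes(cfg)
    gm <- simulate_gene_models(cfg$chrom_length_bp,
                               sim$n_genes %||% 20L,
                               seed = derive_seed(seed, "genes"),
                               exon_mean = sim$exon_mean %||% 200,
                               intron_mean = sim$intron_mean %||% 1500,
                               n_exon_range = sim$n_exon_range %||%
                                 c(3L, 8L))
    if (!is.null(sim$sweep)) {
      cohort <- apply_sweep(cohort, sim$sweep,
                            seed = derive_seed(seed, "sweep"))
    }
    kin_true <- NULL
    if (!is.null(sim$relatedness)) {
      rel <- simulate_relatedness(cohort, sim$relatedness,
                                  seed = derive_seed(seed, "relatedness"))
      cohort <- rel$cohort
      kin_true <- rel$kinship
    }
    ann <- simulate_annotations(cohort, gm,
                                seed = derive_seed(seed, "annotations"))
    trait_spec <- sim$trait %||% list(h2 = 0.3)
    if (!is.null(trait_spec$causal_gene)) {
      ex <- gm$exons[gm$exons$gene_id == trait_spec$causal_gene, ]
      mac <- cohort_mac(cohort)
      pos0 <- cohort$positions_bp - 1L
      in_ex <- in_intervals(pos0, ex)
      mac_lo <- trait_spec$causal_mac_min %||% 3L
      mac_hi <- trait_spec$causal_mac_max %||% 15L
      cand <- which(in_ex & mac >= mac_lo & mac <= mac_hi)
      if (length(cand) < (trait_spec$n_causal %||% 4L)) {
        cand <- which(in_ex & mac >= 2 & mac <= mac_hi)
      }
      ncaus <- min(trait_spec$n_causal %||% 4L, length(cand))
      if (ncaus < 1L) {
        stop("no eligible causal variants in gene ",
             trait_spec$causal_gene, call. = FALSE)
      }
      ci <- with_seed(derive_seed(seed, "causal"),
                      cand[sample.int(length(cand), ncaus)])
      trait_spec$causal_idx <- ci
      # burden drivers are damaging variants (the architecture the testing
      # conditions target): re-annotate the chosen drivers as LoF-class
      # with severity-consistent scores
      pars <- attr(ann, "params")
      ann_new <- with_seed(derive_seed(seed, "causal_annotation"), {
        sev <- sample(lof_compatible_classes(), ncaus, replace = TRUE)
        lofc <- sample(c("HC", "LC"), ncaus, replace = TRUE)
        list(sev = sev, lof = lofc,
             cadd = stats::rgamma(ncaus, shape = pars$cadd$shape,
                                  scale = pars$cadd$scale) +
               pars$cadd$shift[sev],
             eigen = stats::rnorm(ncaus, pars$eigen$mean[sev],
                                  pars$eigen$sd),
             eigenpc = stats::rnorm(ncaus, pars$eigen$mean[sev] * 0.8,
                                    pars$eigen$sd))
      })
      ann$consequence[ci] <- ann_new$sev
      ann$lof[ci] <- ann_new$lof
      ann$cadd[ci] <- unname(ann_new$cadd)
      ann$eigen[ci] <- ann_new$eigen
      ann$eigenpc[ci] <- ann_new$eigenpc
      bet <- trait_spec$beta %||% 2
      trait_spec$beta <- rep_len(bet, ncaus)
    }
    y <- simulate_trait(cohort, kin_true, trait_spec,
                        seed = derive_seed(seed, "trait"))
    traits <- data.frame(sample_id = cohort$sample_ids, trait = unname(y))
    list(cohort = cohort, annotations = ann, gene_models = gm,
         traits = traits, true_kinship = kin_true,
         trait_spec = trait_spec)
  } else {
    inp <- config$inputs
    rd <- read_cohort_vcf(inp$vcf,
                          recomb_rate = config$recomb_rate %||% 1,
                          cM_map = if (!is.null(inp$cm_map_tsv)) {
                            utils::read.table(inp$cm_map_tsv, header = TRUE)
                          })
    exons <- read_bed(inp$exons_bed, "gene_id")
    feats <- if (!is.null(inp$regulatory_bed)) {
      read_bed(inp$regulatory_bed, "feature_id")
    } else NULL
    eqtl <- if (!is.null(inp$eqtl_tsv)) {
      utils::read.table(inp$eqtl_tsv, header = TRUE,
                        stringsAsFactors = FALSE)
    } else NULL
    traits <- utils::read.table(inp$traits_tsv, header = TRUE,
                                stringsAsFactors = FALSE)
    list(cohort = rd$cohort, annotations = rd$annotations,
         gene_models = list(exons = exons, features = feats, eqtl = eqtl),
         traits = traits, true_kinship = NULL, trait_spec = NULL)
  }
}

#' Run the burden scan end to end
#'
#' Simulates or loads a cohort, builds the kinship matrix (LD pruning +
#' centered GRM + self-kinship), fits the null mixed model per trait,
#' builds masks for every gene under every requested condition, runs the
#' variant-set tests, derives the study-wide threshold from the effective
#' number of conditions, and attaches prioritisation flags based on
#' conditioning each suggestive burden on its top single-point variant.
#'
#' @param config list with either a `simulation` block (arguments of
#'   [sim_config()] plus `n_genes`, `trait`, `sweep`, `relatedness`) or an
#'   `inputs` block of file paths; plus optional `conditions` (default all
#'   ten), `suggestive` (default 5e-5), `alpha` (default 0.05), `cluster_r`
#'   (default 0.8), `seed`.
#' @return object of class `burden_scan`: results table, per-condition gene
#'   counts, threshold report, and the stage objects (cohort, annotations,
#'   masks, null fits) for downstream analyses.
#' @export
run_burden_scan <- function(config) {
  validate_run_config(config)
  conditions <- config$conditions %||% burden_conditions()$id
  if (length(conditions) == 0L) {
    stop("empty condition list", call. = FALSE)
  }
  unknown <- setdiff(conditions, burden_conditions()$id)
  if (length(unknown)) stop("unknown condition: ", unknown[1], call. = FALSE)
  stage <- build_stage(config)
  cohort <- stage$cohort
  seed <- config$seed %||% 1L

  prefiltered <- variant_prefilter(cohort)
  common <- which(cohort_maf(cohort) >= 0.05)
  pruned <- ld_prune(cohort, candidate_idx = common)
  kin <- compute_grm(cohort, pruned_indices = pruned)
  eig <- kinship_eigen(kin)

  assignment <- assign_regulatory_to_genes(stage$gene_models$features,
                                           stage$gene_models$exons,
                                           stage$gene_models$eqtl)
  regions <- gene_regions(stage$gene_models$exons,
                          stage$gene_models$features, assignment)
  cadd_med <- stats::median(stage$annotations$cadd, na.rm = TRUE)

  trait_cols <- setdiff(names(stage$traits), "sample_id")
  results <- list(); masks <- list(); nulls <- list()
  for (tr in trait_cols) {
    y <- stage$traits[[tr]]
    null <- fit_null_lmm(y, kinship = kin, eig = eig)
    nulls[[tr]] <- null
    for (cond in conditions) {
      for (g in names(regions)) {
        mk <- build_mask(regions[[g]], cond, cohort, stage$annotations,
                         prefiltered, cadd_median = cadd_med)
        masks[[paste(tr, cond, g, sep = "|")]] <- mk
        if (inherits(mk, "burden_skip")) next
        res <- set_test(null, mk, cohort)
        if (inherits(res, "burden_skip")) next
        top_i <- which.min(res$single_point$p)
        results[[length(results) + 1L]] <- data.frame(
          trait = tr, condition = cond, gene = g,
          n_variants = res$n_variants,
          p = res$p_setO, p_burden = res$p_burden, p_skat = res$p_skat,
          top_variant = res$single_point$variant_id[top_i],
          top_p = res$single_point$p[top_i],
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame(trait = character(0), condition = character(0),
               gene = character(0), n_variants = integer(0), p = numeric(0),
               p_burden = numeric(0), p_skat = numeric(0),
               top_variant = character(0), top_p = numeric(0))

  # conditional on the top single-point variant for suggestive burdens
  suggestive <- config$suggestive %||% 5e-5
  results$cond_top_p <- NA_real_
  for (i in which(results$p <= suggestive)) {
    mk <- masks[[paste(results$trait[i], results$condition[i],
                       results$gene[i], sep = "|")]]
    top_idx <- mk$variant_indices[match(results$top_variant[i],
                                        cohort$variant_ids[mk$variant_indices])]
    ct <- tryCatch(
      conditional_test(nulls[[results$trait[i]]], cohort, mk,
                       list(type = "genotype", variants = top_idx)),
      error = function(e) NULL)
    if (!is.null(ct) && inherits(ct, "set_test_result")) {
      results$cond_top_p[i] <- ct$p_setO
    }
  }
  results <- prioritise(results, suggestive = suggestive)

  gene_counts <- table(results$condition)
  N_mean <- if (length(gene_counts)) mean(gene_counts) else 0
  zmat <- NULL; thr <- NULL
  if (nrow(results) > 0L) {
    first_tr <- trait_cols[1]
    sub <- results[results$trait == first_tr, ]
    genes <- sort(unique(sub$gene))
    zmat <- matrix(NA_real_, length(genes), length(conditions),
                   dimnames = list(genes, conditions))
    for (i in seq_len(nrow(sub))) {
      zmat[sub$gene[i], sub$condition[i]] <- sub$p[i]
    }
    keep <- colSums(!is.na(zmat)) >= 2L
    zsc <- if (any(keep)) zscore_matrix(zmat[, keep, drop = FALSE]) else NULL
    n_eff <- if (!is.null(zsc) && ncol(zsc) >= 1L) {
      effective_conditions(zsc, config$cluster_r %||% 0.8)
    } else structure(1L, eigen_effective = 1)
    thr <- study_wide_threshold(max(N_mean, 1), as.integer(n_eff),
                                length(trait_cols),
                                alpha = config$alpha %||% 0.05)
    thr$n_cond_eff <- as.integer(n_eff)
    thr$n_cond_eigen <- attr(n_eff, "eigen_effective")
  }

  structure(list(results = results, threshold = thr,
                 gene_counts = gene_counts,
                 stage = stage, masks = masks, nulls = nulls,
                 kinship = kin, prefiltered = prefiltered,
                 regions = regions,
                 config = config, config_hash = config_hash(config)),
            class = "burden_scan")
}

#' @export
print.burden_scan <- function(x, ...) {
  cat(sprintf("<burden_scan> %d tests across %d condition(s)\n",
              nrow(x$results), length(unique(x$results$condition))))
  if (!is.null(x$threshold)) {
    cat(sprintf("  study-wide threshold: %.2g (n_cond_eff = %d)\n",
                x$threshold$threshold_2sf, x$threshold$n_cond_eff))
  }
  if (nrow(x$results)) {
    top <- x$results[which.min(x$results$p), ]
    cat(sprintf("  top: %s / %s / %s, p = %.3g [%s]\n", top$gene,
                top$condition, top$trait, top$p, top$flag))
  }
  invisible(x)
}

#' Run the selection scan end to end
#'
#' Site filter, iHS scan, within-bin standardization, gene-level extreme
#' fractions and percentiles under the four region definitions, and
#' (when a second cohort is supplied) gene-level weighted-mean Hudson F_ST
#' with percentiles.
#'
#' @param config list with a `simulation` block or `inputs`, plus optional
#'   `definitions` (default 1:4), `cohort2` (a second `cohort` for F_ST),
#'   `prune_relatives` (default FALSE), `seed`.
#' @return object of class `selection_scan`: standardized iHS records,
#'   per-gene fraction tables per definition, and F_ST table when
#'   available.
#' @export
run_selection_scan <- function(config) {
  validate_run_config(config)
  stage <- build_stage(config)
  cohort <- stage$cohort
  if (is.null(stage$annotations)) {
    stop("selection scan requires annotations (ancestral allele and ",
         "mappability)", call. = FALSE)
  }
  if (isTRUE(config$prune_relatives)) {
    common <- which(cohort_maf(cohort) >= 0.05)
    pruned <- ld_prune(cohort, candidate_idx = common)
    ph <- estimate_pihat(cohort, pruned)
    keep <- prune_related(ph, seed = derive_seed(config$seed %||% 1L,
                                                 "prune"),
                          sample_ids = cohort$sample_ids)
    cohort <- cohort_subset(cohort, keep)
  }
  sites <- selection_site_filter(cohort, stage$annotations)
  if (!length(sites)) stop("no sites pass the selection filter",
                           call. = FALSE)
  recs <- ihs_scan(cohort, sites)
  recs <- standardize_ihs(recs, n_haplotypes = nrow(cohort$haplotypes))
  assignment <- assign_regulatory_to_genes(stage$gene_models$features,
                                           stage$gene_models$exons,
                                           stage$gene_models$eqtl)
  regions <- gene_regions(stage$gene_models$exons,
                          stage$gene_models$features, assignment)
  defs <- config$definitions %||% 1:4
  fractions <- lapply(defs, function(d) {
    fr <- gene_fraction_extreme(recs, cohort, regions, definition = d)
    if (nrow(fr)) {
      fr$percentile <- vapply(fr$gene_id, function(g) {
        gene_percentile(fr, g)
      }, 0)
    }
    fr
  })
  names(fractions) <- paste0("def", defs)
  fst <- NULL
  if (!is.null(config$cohort2)) {
    fst <- gene_fst(cohort, config$cohort2, regions,
                    definition = max(defs), sites = sites)
    if (nrow(fst)) {
      fst$percentile <- vapply(fst$gene_id, function(g) {
        gene_percentile(fst, g, stat = "fst")
      }, 0)
    }
  }
  structure(list(records = recs, fractions = fractions, fst = fst,
                 regions = regions, cohort = cohort,
                 config = config, config_hash = config_hash(config)),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf("<selection_scan> %d iHS records, %d gene table(s)\n",
              nrow(x$records), length(x$fractions)))
  fr <- x$fractions[[length(x$fractions)]]
  if (nrow(fr)) {
    top <- fr[which.max(fr$frac_extreme), ]
    cat(sprintf("  top gene %s: frac |iHS|>2 = %.2f (%.1f percentile)\n",
                top$gene_id, top$frac_extreme, top$percentile))
  }
  invisible(x)
}
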