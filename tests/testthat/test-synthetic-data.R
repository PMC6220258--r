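# The synthetic cohort generator: determinism, founder closure, SFS shape,
# sweeps, pedigree relatedness and trait construction.

test_that("identical seeds give bit-identical cohorts", {
  cfg <- sim_config(n_samples = 40, n_variants = 400,
                    chrom_length_bp = 1e6, seed = 7)
  expect_identical(simulate_haplotypes(cfg), simulate_haplotypes(cfg))
  cfg2 <- sim_config(n_samples = 40, n_variants = 400,
                     chrom_length_bp = 1e6, seed = 8)
  expect_false(identical(simulate_haplotypes(cfg),
                         simulate_haplotypes(cfg2)))
})

test_that("two founders: every site shows only the founder alleles", {
  cfg <- sim_config(n_samples = 30, n_variants = 300,
                    chrom_length_bp = 1e6, n_founder_haplotypes = 2,
                    private_frac = 0, seed = 3)
  co <- simulate_haplotypes(cfg)
  # with 2 founders and no private mutations, each column carries at most
  # the two founder alleles; allele count at a site is 0, those on founder
  # 1, founder 2, or both - so per-column haplotype patterns come from at
  # most 2 distinct sequences locally
  expect_true(all(co$haplotypes %in% c(0L, 1L)))
  # every haplotype must be reconstructible as a founder mosaic: at any
  # site the set of sample alleles is a subset of founder alleles; since
  # founder alleles are {0,1} we check segments: adjacent identical
  # columns in founders imply identical columns in samples
  ac <- colSums(co$haplotypes)
  expect_true(all(ac %in% c(0L, nrow(co$haplotypes)) |
                    (ac > 0 & ac < nrow(co$haplotypes))))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = -5), "n_samples")
  expect_error(sim_config(n_founder_haplotypes = 1), "n_founder")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(sweep_spec = list(carrier_frac = 2)),
               "carrier_frac")
})

test_that("MAC=1 fraction matches a direct allele count over the written VCF", {
  co <- small_cohort()
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  write_cohort_vcf(co, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  gt_mac <- vapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gts <- f[-(1:9)]
    al <- unlist(strsplit(gts, "|", fixed = TRUE))
    ac <- sum(al == "1")
    min(ac, length(al) - ac)
  }, 0, USE.NAMES = FALSE)
  frac_oracle <- mean(gt_mac == 1)
  frac_pkg <- mean(cohort_mac(co) == 1)
  expect_equal(frac_pkg, frac_oracle, tolerance = 1e-12)
  expect_gt(frac_oracle, 0.05)
})

test_that("isolate default is rare-enriched beyond the cosmopolitan preset", {
  co_iso <- simulate_haplotypes(sim_config(n_samples = 400,
                                           n_variants = 6000,
                                           chrom_length_bp = 1.5e7,
                                           seed = 101))
  co_cos <- simulate_haplotypes(sim_config(n_samples = 400,
                                           n_variants = 6000,
                                           chrom_length_bp = 1.5e7,
                                           preset = "cosmopolitan",
                                           seed = 101))
  f_iso <- mean(cohort_maf(co_iso) < 0.01, na.rm = TRUE)
  f_cos <- mean(cohort_maf(co_cos) < 0.01, na.rm = TRUE)
  expect_gt(f_iso, 0.5)       # majority of variants rare
  expect_gt(f_iso, f_cos)     # isolate preset more rare-enriched
})

test_that("sweep: zero carrier fraction is a no-op; frequency and identity", {
  co <- small_cohort()
  spec0 <- list(core_bp = 4e6, carrier_frac = 0, copy_length_bp = 5e5)
  expect_identical(apply_sweep(co, spec0, seed = 1), co)

  spec <- list(core_bp = 4e6, carrier_frac = 0.4, copy_length_bp = 5e5)
  sw <- apply_sweep(co, spec, seed = 1)
  core <- attr(sw, "sweep_core")
  derived <- if (sw$ancestral_is_ref[core]) 1L else 0L
  daf <- mean(sw$haplotypes[, core] == derived)
  expect_equal(daf, 0.4, tolerance = 1 / nrow(sw$haplotypes))

  # mean pairwise identity in the window: carriers exceed non-carriers
  win <- which(abs(sw$positions_bp - sw$positions_bp[core]) <= 5e5)
  carr <- which(sw$haplotypes[, core] == derived)
  nonc <- which(sw$haplotypes[, core] != derived)
  pair_ident <- function(rows) {
    rows <- rows[1:min(20, length(rows))]
    H <- sw$haplotypes[rows, win, drop = FALSE]
    tot <- 0; np <- 0
    for (a in 1:(nrow(H) - 1)) for (b in (a + 1):nrow(H)) {
      tot <- tot + mean(H[a, ] == H[b, ]); np <- np + 1
    }
    tot / np
  }
  expect_gt(pair_ident(carr), pair_ident(nonc))
})

test_that("relatedness constructions give pedigree-expected kinship and IBD", {
  cfg <- sim_config(n_samples = 80, n_variants = 3000,
                    chrom_length_bp = 5e6, seed = 21)
  co <- simulate_haplotypes(cfg)
  rel <- simulate_relatedness(
    co, list(list(type = "duplicate", count = 2),
             list(type = "parent_offspring", count = 3),
             list(type = "sib", count = 10)), seed = 4)
  phi <- rel$kinship
  prs <- rel$pairs
  dup <- prs[prs$type == "duplicate", ]
  expect_true(all(phi[cbind(dup$id1, dup$id2)] == 0.5))
  po <- prs[prs$type == "parent_offspring", ]
  expect_true(all(phi[cbind(po$id1, po$id2)] == 0.25))
  sib <- prs[prs$type == "sib", ]
  expect_true(all(phi[cbind(sib$id1, sib$id2)] == 0.25))
  # duplicates share identical genomes
  expect_identical(rel$cohort$dosages[dup$id1[1], ],
                   rel$cohort$dosages[dup$id2[1], ])

  # IBD2 fraction for sibs ~ 0.25 by direct counting on recorded meioses
  tr <- rel$transmissions
  child_of <- vapply(tr, function(t) t$child, 0)
  ibd2 <- vapply(seq_len(nrow(sib)), function(i) {
    t1 <- tr[[match(sib$id1[i], child_of)]]
    t2 <- tr[[match(sib$id2[i], child_of)]]
    mean(t1$origin[1, ] == t2$origin[1, ] &
           t1$origin[2, ] == t2$origin[2, ])
  }, 0)
  expect_lt(abs(mean(ibd2) - 0.25), 0.08)
  # requesting more pairs than samples errors
  expect_error(simulate_relatedness(co, list(list(type = "sib",
                                                  count = 200)), seed = 1),
               "more pairs")
})

test_that("annotations respect position classes and severity shifts", {
  cfg <- sim_config(n_samples = 60, n_variants = 12000,
                    chrom_length_bp = 6e6, seed = 33)
  co <- simulate_haplotypes(cfg)
  gm <- simulate_gene_models(6e6, 20, seed = 33)
  ann <- simulate_annotations(co, gm, seed = 33)
  pos0 <- co$positions_bp - 1L
  outside <- !rarescan:::in_intervals(pos0, gm$exons) &
    ann$regulatory == ""
  expect_true(all(ann$consequence[outside] == "intergenic"))
  expect_true(all(ann$regulatory[ann$consequence == "intergenic"] == ""))
  # HC LoF only on LoF-compatible consequences
  hc <- ann$lof == "HC"
  expect_true(all(ann$consequence[hc] %in%
                    c("splice_acceptor", "splice_donor", "stop_gained",
                      "frameshift")))
  # severity shift recovered: stop_gained CADD above synonymous
  m_stop <- mean(ann$cadd[ann$consequence == "stop_gained"])
  m_syn <- mean(ann$cadd[ann$consequence == "synonymous"])
  expect_gt(m_stop, m_syn)
})

test_that("trait generator: null, OLS recovery and scaling", {
  co <- small_cohort()
  n <- length(co$sample_ids)
  # null trait: no correlation with any dosage
  y0 <- simulate_trait(co, NULL, list(h2 = 0), seed = 5)
  j <- which(cohort_maf(co) > 0.1)[1]
  expect_lt(abs(cor(y0, co$dosages[, j])), 3 / sqrt(n))
  expect_equal(simulate_trait(co, NULL, list(h2 = 0), seed = 5), y0)

  # single causal variant recovered by OLS across replicates
  mac <- cohort_mac(co)
  jc <- which(mac >= 5 & mac <= 8)[1]
  est <- vapply(1:60, function(r) {
    y <- simulate_trait(co, NULL, list(h2 = 0, causal_idx = jc, beta = 2.5),
                        seed = 1000 + r)
    unname(coef(lm(y ~ co$dosages[, jc]))[2])
  }, 0)
  expect_lt(abs(mean(est) - 2.5), 3 * sd(est) / sqrt(60))
  expect_error(simulate_trait(co, NULL, list(h2 = 2)), "h2")
})

test_that("h2=1 trait covariance matches 2K within Monte-Carlo error", {
  cfg <- sim_config(n_samples = 50, n_variants = 400,
                    chrom_length_bp = 1e6, seed = 12)
  rel <- simulate_relatedness(simulate_haplotypes(cfg),
                              list(list(type = "sib", count = 8)), seed = 2)
  R <- 400
  Y <- vapply(seq_len(R), function(r) {
    simulate_trait(rel$cohort, rel$kinship, list(h2 = 1, sigma_e = 0),
                   seed = r)
  }, numeric(50))
  C <- cov(t(Y))
  K2 <- 2 * rel$kinship
  ut <- upper.tri(C)
  # entrywise MC error ~ sqrt(2/R); allow 5 sigma on the max over entries
  expect_lt(max(abs(C - K2)[ut]), 5 * sqrt(2 / R))
  expect_lt(abs(mean(diag(C)) - 1), 0.1)
})
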