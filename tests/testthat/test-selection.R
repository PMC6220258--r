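# EHH/iHS selection scan against brute-force oracles, standardization,
# gene fractions, percentiles and Hudson F_ST.

test_that("selection site filter matches hand enumeration of its rules", {
  set.seed(59)
  H <- matrix(rbinom(40 * 10, 1, 0.4), 40, 10)
  H[, 4] <- c(1L, rep(0L, 39))                    # MAF 0.0125 < 0.05
  co <- make_cohort(H)
  co$alt[1] <- "TT"                               # INDEL-like allele
  co$ancestral_is_ref[2] <- NA                    # no ancestral annotation
  ann <- data.frame(mappability = c(rep(1, 9), 0.5))  # low mappability
  kept <- selection_site_filter(co, ann)
  expect_false(any(c(1L, 2L, 4L, 10L) %in% kept))
  # hand enumeration of the survivors
  maf <- cohort_maf(co)
  cand <- which(nchar(co$alt) == 1 & !is.na(co$ancestral_is_ref) &
                  maf >= 0.05 & ann$mappability >= 0.8)
  hw_ok <- vapply(cand, function(j) {
    d <- co$dosages[, j]
    hwe_midp(sum(d == 0), sum(d == 1), sum(d == 2)) >= 1e-30
  }, TRUE)
  expect_setequal(kept, cand[hw_ok])
})

test_that("EHH trivial cases behave as defined", {
  # all carriers identical over the window -> EHH stays 1
  H <- rbind(matrix(1L, 4, 5), matrix(rbinom(20, 1, 0.5), 4, 5))
  H[1:4, 3] <- 1L; H[5:8, 3] <- 0L
  curve <- ehh(H, core = 3, allele = 1, side = "right")
  expect_true(all(curve$ehh == 1))
  # two carriers differing at the adjacent site -> EHH drops to 0
  H2 <- matrix(0L, 4, 4)
  H2[1:2, 2] <- 1L
  H2[1, 3] <- 1L
  c2 <- ehh(H2, core = 2, allele = 1, side = "right")
  expect_equal(c2$ehh, c(1, 0, 0))
  # fewer than 2 carriers -> undefined
  H3 <- matrix(0L, 4, 3); H3[1, 2] <- 1L
  expect_null(ehh(H3, core = 2, allele = 1))
})

test_that("ehh equals the all-pairs identity oracle", {
  set.seed(60)
  for (rep in 1:8) {
    nh <- sample(c(6, 12, 20), 1)
    m <- sample(c(15, 30), 1)
    H <- matrix(rbinom(nh * m, 1, runif(1, 0.2, 0.6)), nh, m)
    core <- sample(3:(m - 2), 1)
    for (allele in 0:1) {
      for (side in c("right", "left")) {
        o <- oracle_ehh(H, core, allele, side)
        got <- ehh(H, core, allele, side)
        if (is.null(o)) {
          expect_null(got)
        } else {
          expect_equal(got$ehh, o$ehh, tolerance = 1e-12)
          expect_identical(got$site, o$site)
          expect_true(all(diff(got$ehh) <= 1e-12))   # nonincreasing
        }
      }
    }
  }
})

test_that("unstandardized iHS equals the naive implementation to 1e-9", {
  set.seed(61)
  for (rep in 1:12) {
    nh <- sample(c(12, 24, 40), 1)
    m <- sample(c(40, 100), 1)
    H <- matrix(rbinom(nh * m, 1, runif(1, 0.25, 0.6)), nh, m)
    co <- make_cohort(H, pos_bp = sort(sample.int(5e6, m)))
    co$ancestral_is_ref <- runif(m) < 0.8
    core <- sample(5:(m - 4), 1)
    got <- unstandardized_ihs(co, core)
    want <- oracle_ihs(co, core)
    expect_equal(got$defined, want$defined)
    if (want$defined) {
      expect_equal(got$raw_ihs, want$raw_ihs, tolerance = 1e-9)
      expect_equal(got$ihh_d, want$ihh_d, tolerance = 1e-9)
      expect_equal(got$ihh_a, want$ihh_a, tolerance = 1e-9)
      expect_identical(got$edge, want$edge)
    }
  }
  # mirror-identical decay on both alleles -> raw iHS exactly 0
  H <- rbind(matrix(rep(c(1L, 0L), 10), 4, 20, byrow = TRUE),
             matrix(rep(c(1L, 0L), 10), 4, 20, byrow = TRUE))
  H[1:4, 10] <- 1L; H[5:8, 10] <- 0L
  H[c(1, 3, 5, 7), 12] <- 1L - H[c(1, 3, 5, 7), 12]
  H[c(1, 3, 5, 7), 8] <- 1L - H[c(1, 3, 5, 7), 8]
  co <- make_cohort(H)
  r <- unstandardized_ihs(co, 10)
  expect_equal(r$raw_ihs, 0, tolerance = 1e-12)
})

test_that("sweep cores show negative raw iHS (long derived haplotypes)", {
  ok <- 0
  for (s in 1:6) {
    cfg <- sim_config(n_samples = 120, n_variants = 2000,
                      chrom_length_bp = 8e6, seed = s)
    co <- simulate_haplotypes(cfg)
    co <- apply_sweep(co, list(core_bp = 4e6, carrier_frac = 0.45,
                               copy_length_bp = 5e5), seed = s)
    r <- unstandardized_ihs(co, attr(co, "sweep_core"))
    if (r$defined && r$raw_ihs < 0) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("standardize_ihs: per-bin moments, degenerate input, bin merging", {
  set.seed(62)
  recs <- data.frame(site = 1:300, raw_ihs = rnorm(300),
                     ihh_d = 1, ihh_a = 1,
                     dac = sample(1:199, 300, replace = TRUE),
                     edge = FALSE)
  std <- standardize_ihs(recs, n_haplotypes = 200)
  for (b in unique(std$bin)) {
    v <- std$std_ihs[std$bin == b]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-9)
  }
  # one record per bin everywhere -> error
  lone <- data.frame(site = 1:5, raw_ihs = rnorm(5), ihh_d = 1, ihh_a = 1,
                     dac = c(1, 50, 100, 150, 199), edge = FALSE)
  expect_error(standardize_ihs(lone, n_haplotypes = 200), "degenerate")
  expect_error(standardize_ihs(recs[0, ], 200), "no iHS records")
})

test_that("gene fractions count extreme SNVs per region definition", {
  recs <- data.frame(site = 1:10, std_ihs = c(3, -3, 2.5, rep(0.5, 7)),
                     dac = 5, raw_ihs = 0)
  H <- matrix(0L, 4, 10)
  co <- make_cohort(H, pos_bp = seq(100L, 1000L, by = 100L))
  exons <- data.frame(gene_id = c("A", "B"), start = c(50L, 850L),
                      end = c(1050L, 1080L))
  rg <- gene_regions(exons)
  fr <- gene_fraction_extreme(recs, co, rg, definition = 1)
  expect_equal(fr$frac_extreme[fr$gene_id == "A"], 0.3)   # 3 of 10
  expect_equal(fr$frac_extreme[fr$gene_id == "B"], 0)     # none extreme
})

test_that("gene percentiles use midranks and matched subsets", {
  fr <- data.frame(gene_id = sprintf("g%03d", 1:100),
                   n_snvs = rep(10L, 100),
                   frac_extreme = c(seq(0, 0.98, length.out = 99), 1))
  expect_equal(gene_percentile(fr, "g100"), 99.5)  # unique maximum
  fr2 <- fr; fr2$frac_extreme <- 0.5
  expect_equal(gene_percentile(fr2, "g050"), 50)   # all ties
  # matched mode with tol = 0 keeps only equal SNV counts
  fr3 <- fr
  fr3$n_snvs <- rep(c(10L, 20L), 50)
  pct <- gene_percentile(fr3, "g002", matched = TRUE, tol = 0)
  expect_equal(pct, gene_percentile(fr3[fr3$n_snvs == 20L, ], "g002"))
  expect_error(gene_percentile(fr, "nope"), "not present")
})

test_that("Hudson F_ST per-SNP components match the formula", {
  expect_equal(unlist(hudson_fst_snp(1, 10, 0, 10)),
               c(numerator = 1, denominator = 1))
  r <- hudson_fst_snp(0.5, 10, 0.5, 10)
  expect_equal(r$numerator, -0.25 / 9 * 2, tolerance = 1e-12)  # -0.0556
  expect_equal(r$denominator, 0.5)
  big <- hudson_fst_snp(0.3, 1e9, 0.3, 1e9)
  expect_lt(abs(big$numerator), 1e-8)              # n -> infinity limit
  expect_error(hudson_fst_snp(0.5, 1, 0.5, 10), "exceed 1")
  expect_error(hudson_fst_snp(1.2, 10, 0.5, 10), "frequencies")
})

test_that("weighted mean F_ST is the ratio of averages", {
  one <- data.frame(numerator = 0.3, denominator = 0.6)
  expect_equal(weighted_mean_fst(one), 0.5)
  two <- data.frame(numerator = c(1, 0), denominator = c(1, 1))
  expect_equal(weighted_mean_fst(two), 0.5)
  three <- data.frame(numerator = c(1, 0, 0), denominator = c(1, 1, 2))
  expect_equal(weighted_mean_fst(three), 0.25)     # != mean of ratios 1/3
  expect_true(is.na(weighted_mean_fst(
    data.frame(numerator = 1, denominator = 0))))
  # naive-loop oracle on random components
  set.seed(63)
  comp <- data.frame(numerator = rnorm(1000, 0.02, 0.05),
                     denominator = runif(1000, 0.1, 0.5))
  tot_n <- 0; tot_d <- 0
  for (i in 1:1000) {
    tot_n <- tot_n + comp$numerator[i]
    tot_d <- tot_d + comp$denominator[i]
  }
  expect_equal(weighted_mean_fst(comp), tot_n / tot_d, tolerance = 1e-12)
})

test_that("F_ST is near zero between panmictic subsamples", {
  cfg <- sim_config(n_samples = 200, n_variants = 12000,
                    chrom_length_bp = 2e7, private_frac = 0.2,
                    founder_spectrum_gamma = 0.5, seed = 64)
  co <- simulate_haplotypes(cfg)
  set.seed(64)
  idx <- sample(200, 100)
  co1 <- cohort_subset(co, idx)
  co2 <- cohort_subset(co, setdiff(1:200, idx))
  maf <- cohort_maf(co)
  sites <- which(maf >= 0.05)
  expect_gte(length(sites), 5000)
  p1 <- colMeans(co1$dosages[, sites]) / 2
  p2 <- colMeans(co2$dosages[, sites]) / 2
  comp <- hudson_fst_snp(p1, 200, p2, 200)
  expect_lt(abs(weighted_mean_fst(comp)), 0.01)
})
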