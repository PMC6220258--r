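# Variant selection and weighting: Phred ranks, Eigen shifts, HWE mid-p,
# pre-filters, regulatory assignment and the ten-condition mask builder.

test_that("phred_scale maps ranks to -10*log10(rank/N)", {
  x <- 1:100
  w <- phred_scale(x)
  expect_equal(w[which.max(x)], 20)             # top of N=100 -> 20.0
  expect_true(all(w > 0))                       # bottom floored above 0
  expect_lt(w[which.min(x)], 1e-5)
  expect_error(phred_scale(numeric(0)), "empty")
})

test_that("phred_scale is monotone with mean-rank ties (brute force)", {
  set.seed(42)
  for (rep in 1:20) {
    x <- sample(round(rnorm(30), 1))            # induces ties
    w <- phred_scale(x)
    # brute-force mean descending ranks
    rk <- vapply(x, function(v) sum(x > v) + (sum(x == v) + 1) / 2, 0)
    w_oracle <- pmax(-10 * log10(rk / length(x)), 1e-6)
    expect_equal(w, w_oracle, tolerance = 1e-12)
    o <- order(x, decreasing = TRUE)
    expect_true(all(diff(w[o]) <= 1e-12))
  }
})

test_that("shift_eigen adds 1 and floors non-positive results at epsilon", {
  expect_equal(shift_eigen(0.5), 1.5)
  expect_equal(shift_eigen(-3), 1e-6)
  expect_equal(shift_eigen(-1), 1e-6)           # boundary: 0 not allowed
  expect_true(all(shift_eigen(rnorm(100)) > 0))
})

test_that("hwe_midp matches exact enumeration and handles degeneracy", {
  expect_gte(hwe_midp(25, 50, 25), 0.5)         # mode of the distribution
  expect_equal(hwe_midp(1, 0, 0), 1)            # single-genotype case
  expect_error(hwe_midp(0, 0, 0), "all-zero")
  expect_equal(hwe_midp(90, 0, 10), oracle_hwe_midp(90, 0, 10),
               tolerance = 1e-12)
  expect_lt(hwe_midp(90, 0, 10), 1e-5)
  # random cases against the independent enumeration
  set.seed(3)
  for (rep in 1:25) {
    cnt <- as.vector(rmultinom(1, 60, c(0.5, 0.3, 0.2)))
    expect_equal(hwe_midp(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe_midp(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
})

test_that("variant_prefilter enforces MAF, missingness and HWE bounds", {
  # 6 samples won't do: construct 100 samples with controlled columns
  n <- 100
  D <- matrix(0L, n, 4)
  D[1:20, 1] <- 1L                      # MAF 0.10 -> excluded (>= 0.05)
  D[1:6, 2] <- 1L                       # MAF 0.03, in HWE -> kept
  D[1:3, 3] <- 1L; D[4:5, 3] <- NA     # 2% missing -> excluded
  D[1:4, 4] <- 2L                       # 4 hom-alt, 0 het -> HWE fails
  co <- make_cohort(matrix(0L, 2 * n, 4))
  co$dosages <- D
  kept <- variant_prefilter(co)
  expect_identical(kept, 2L)
  expect_lt(hwe_midp(96, 0, 4), 1e-5)   # the column-4 case
})

test_that("regulatory features map to genes by overlap or eQTL link", {
  exons <- data.frame(gene_id = c("A", "A", "B"),
                      start = c(100L, 300L, 1000L),
                      end = c(200L, 400L, 1100L))
  feats <- data.frame(feature_id = c("f1", "f2", "f3"),
                      start = c(150L, 600L, 5000L),
                      end = c(260L, 700L, 5100L))
  eqtl <- data.frame(pos_bp = 650L, gene_id = c("A", "B"))
  asg <- assign_regulatory_to_genes(feats, exons,
                                    rbind(eqtl,
                                          data.frame(pos_bp = 650L,
                                                     gene_id = "B")[0, ]))
  expect_equal(asg$f1, "A")                       # hull overlap only
  asg2 <- assign_regulatory_to_genes(feats, exons, eqtl)
  expect_setequal(asg2$f2, c("A", "B"))           # multi-gene eQTL
  expect_false("f3" %in% names(asg2))             # overlaps nothing
})

test_that("gene regions nest across the four definitions", {
  exons <- data.frame(gene_id = "G", start = c(100L, 500L),
                      end = c(200L, 650L))
  feats <- data.frame(feature_id = "f", start = 2000L, end = 2200L)
  rg <- gene_regions(exons, feats, list(f = "G"))$G
  expect_equal(rg$exons$start, c(100L, 500L))
  expect_equal(rg$exons50$start, c(50L, 450L))
  pos <- seq(0L, 2500L, by = 10L)
  d1 <- rarescan:::in_intervals(pos, rg$def1)
  d2 <- rarescan:::in_intervals(pos, rg$def2)
  d3 <- rarescan:::in_intervals(pos, rg$def3)
  d4 <- rarescan:::in_intervals(pos, rg$def4)
  expect_true(all(!d1 | d2))   # def1 subset of def2
  expect_true(all(!d1 | d3))   # def1 subset of def3 (hull)
  expect_true(all(!d3 | d4))   # def3 subset of def4
  expect_true(all(!d2 | d4))
})

test_that("build_mask applies the condition filters, weights and min-2 rule", {
  n <- 50; m <- 8
  set.seed(11)
  H <- matrix(rbinom(2 * n * m, 1, 0.02), 2 * n, m)
  co <- make_cohort(H, pos_bp = c(110L, 120L, 130L, 140L, 150L, 160L,
                                  900L, 950L))
  ann <- data.frame(
    variant_id = co$variant_ids,
    consequence = c("stop_gained", "missense", "splice_donor", "synonymous",
                    "missense", "frameshift", "regulatory", "regulatory"),
    lof = c("HC", "none", "LC", "none", "none", "HC", "none", "none"),
    cadd = c(20, 5, 15, 1, 9, 25, 3, 2),
    eigen = c(2, 0.3, 1.5, -2, 0.8, 2.5, 0.6, -0.4),
    eigenpc = c(1.5, 0.2, 1.2, -1, 0.5, 2, 0.4, -0.2),
    mappability = 1,
    regulatory = c(rep("", 6), "f", "f"),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "G", start = 100L, end = 200L)
  feats <- data.frame(feature_id = "f", start = 890L, end = 960L)
  rg <- gene_regions(exons, feats, list(f = "G"))$G
  pre <- 1:8

  hc <- build_mask(rg, "LOFTEE_HC", co, ann, pre)
  expect_setequal(hc$variant_indices, c(1L, 6L))
  expect_true(all(hc$weights == 1))

  lc <- build_mask(rg, "LOFTEE_LC", co, ann, pre)
  expect_true(all(hc$variant_indices %in% lc$variant_indices))  # nesting
  expect_setequal(lc$variant_indices, c(1L, 3L, 6L))

  sv <- build_mask(rg, "EXON_SEVERE", co, ann, pre)
  expect_false(2L %in% sv$variant_indices)       # missense excluded
  expect_true(3L %in% sv$variant_indices)        # splice donor included
  expect_false(4L %in% sv$variant_indices)       # synonymous excluded

  cadd_all <- build_mask(rg, "EXON_CADD", co, ann, pre)
  med <- median(ann$cadd)
  cadd_med <- build_mask(rg, "EXON_CADD_MEDIAN", co, ann, pre,
                         cadd_median = med)
  expect_true(all(cadd_med$variant_indices %in% cadd_all$variant_indices))
  expect_true(all(ann$cadd[cadd_med$variant_indices] >= med))
  expect_equal(cadd_all$weights, ann$cadd[cadd_all$variant_indices])

  reg <- build_mask(rg, "REG_EIGENPHRED", co, ann, pre)
  expect_setequal(reg$variant_indices, c(7L, 8L))
  expect_true(all(reg$weights > 0))

  er <- build_mask(rg, "EXONREG_EIGEN", co, ann, pre)
  expect_true(all(c(cadd_all$variant_indices, 7L, 8L) %in%
                    er$variant_indices))
  expect_equal(er$weights, shift_eigen(ann$eigen[er$variant_indices]))

  # min-2 rule: restrict the universe to a single HC variant
  skip_mask <- build_mask(rg, "LOFTEE_HC", co, ann, prefiltered = c(1L, 2L))
  expect_s3_class(skip_mask, "burden_skip")
  expect_error(build_mask(rg, "NOT_A_CONDITION", co, ann, pre), "condition")
  expect_equal(nrow(burden_conditions()), 10L)
})
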