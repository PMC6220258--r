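# GRM estimation, LD pruning, pi-hat and relative exclusion.

rel_fixture <- function() {
  get_fixture("rel_fixture", function() {
    cfg <- sim_config(n_samples = 150, n_variants = 8000,
                      chrom_length_bp = 1.5e7, n_founder_haplotypes = 300,
                      founder_spectrum_gamma = 0.4, private_frac = 0.15,
                      mosaic_generations = 40, seed = 55)
    co <- simulate_haplotypes(cfg)
    rel <- simulate_relatedness(
      co, list(list(type = "duplicate", count = 2),
               list(type = "parent_offspring", count = 5),
               list(type = "sib", count = 10)), seed = 6)
    common <- which(cohort_maf(rel$cohort) >= 0.05)
    pruned <- ld_prune(rel$cohort, candidate_idx = common)
    c(rel, list(pruned = pruned))
  })
}

test_that("GRM: duplicates near 1, unrelated centered, diagonal near 1", {
  fx <- rel_fixture()
  kin <- compute_grm(fx$cohort, pruned_indices = fx$pruned)
  K <- kin$matrix
  dup <- fx$pairs[fx$pairs$type == "duplicate", ]
  expect_true(all(abs(K[cbind(dup$id1, dup$id2)] - 1) < 0.08))
  # samples 33-120 are untouched: sources come off the front (1-32),
  # pedigree slots off the back (124-150)
  founders <- 35:120
  off <- K[founders, founders][upper.tri(diag(length(founders)))]
  # centered GRM carries a structural O(1/n) negative off-diagonal offset;
  # "~ 0" means small at the scale of true relatedness (0.25-1)
  expect_lt(abs(mean(off)), 0.01)
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
  expect_error(compute_grm(fx$cohort, maf_min = 0.9), "no variants")
})

test_that("GRM recovers pedigree kinship on a founder-rich cohort", {
  # n >= 300 samples, >= 10,000 common variants
  cfg <- sim_config(n_samples = 320, n_variants = 20000,
                    chrom_length_bp = 3e7, n_founder_haplotypes = 600,
                    founder_spectrum_gamma = 0.3, private_frac = 0.1,
                    mosaic_generations = 60, seed = 11)
  co <- simulate_haplotypes(cfg)
  rel <- simulate_relatedness(
    co, list(list(type = "sib", count = 50),
             list(type = "parent_offspring", count = 15),
             list(type = "duplicate", count = 5)), seed = 5)
  common <- which(cohort_maf(rel$cohort) >= 0.05)
  expect_gte(length(common), 10000)
  pruned <- ld_prune(rel$cohort, candidate_idx = common)
  kin <- compute_grm(rel$cohort, pruned_indices = pruned)
  ut <- upper.tri(kin$matrix)
  expect_gt(cor(kin$matrix[ut], (2 * rel$kinship)[ut]), 0.9)
})

test_that("ld_prune removes duplicated columns and keeps independents", {
  set.seed(9)
  n <- 60
  X <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  X[, 4] <- X[, 3]                      # duplicated column
  co <- make_cohort(matrix(0L, 2 * n, 10),
                    pos_bp = seq(1000L, by = 100L, length.out = 10))
  co$dosages <- X
  kept <- ld_prune(co, r2_max = 0.2, window_bp = 1e4)
  expect_true(3L %in% kept)
  expect_false(4L %in% kept)            # exactly one of the pair survives

  # mutually independent columns all survive (r2 below threshold)
  X2 <- matrix(rbinom(n * 8, 2, 0.4), n, 8)
  co2 <- make_cohort(matrix(0L, 2 * n, 8),
                     pos_bp = seq(1000L, by = 100L, length.out = 8))
  co2$dosages <- X2
  r2max <- max(cor(X2)[upper.tri(diag(8))]^2)
  kept2 <- ld_prune(co2, r2_max = max(0.5, r2max + 0.01), window_bp = 1e4)
  expect_identical(kept2, 1:8)
})

test_that("ld_prune equals brute-force greedy pruning on a 50-variant instance", {
  set.seed(14)
  n <- 80; m <- 50
  X <- matrix(rbinom(n * m, 2, 0.3), n, m)
  X[, 10] <- X[, 9]; X[, 25] <- pmin(X[, 24] + rbinom(n, 1, 0.05), 2)
  pos <- sort(sample.int(5e5, m))
  co <- make_cohort(matrix(0L, 2 * n, m), pos_bp = pos)
  co$dosages <- X
  kept <- ld_prune(co, r2_max = 0.2, window_bp = 1e5)
  # oracle: same greedy semantics, all pairs checked directly
  oracle_kept <- integer(0)
  for (j in 1:m) {
    drop <- FALSE
    for (k in oracle_kept) {
      if (pos[j] - pos[k] <= 1e5) {
        r2 <- suppressWarnings(cor(X[, k], X[, j]))^2
        if (!is.na(r2) && r2 > 0.2) drop <- TRUE
      }
    }
    if (!drop) oracle_kept <- c(oracle_kept, j)
  }
  expect_identical(kept, oracle_kept)
})

test_that("pi-hat matches pedigree expectations", {
  fx <- rel_fixture()
  ph <- estimate_pihat(fx$cohort, fx$pruned)
  expect_s3_class(ph, "pihat_table")
  ids <- fx$cohort$sample_ids
  lookup <- function(i, j) {
    a <- ids[i]; b <- ids[j]
    ph$pihat[(ph$id1 == a & ph$id2 == b) | (ph$id1 == b & ph$id2 == a)]
  }
  prs <- fx$pairs
  for (i in which(prs$type == "duplicate")) {
    expect_gte(lookup(prs$id1[i], prs$id2[i]), 0.95)
  }
  po <- vapply(which(prs$type == "parent_offspring"),
               function(i) lookup(prs$id1[i], prs$id2[i]), 0)
  expect_true(all(abs(po - 0.5) < 0.05))
  expect_true(all(ph$pihat >= 0 & ph$pihat <= 1 + 1e-9))

  # unrelated samples with independent sites: pi-hat stays near zero
  # (the mosaic cohort carries genuine founder coancestry, so the clean
  # bound is checked on iid genotypes)
  set.seed(77)
  n <- 60; m <- 20000
  p <- runif(m, 0.1, 0.5)
  D <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  co_iid <- make_cohort(matrix(0L, 2 * n, m),
                        pos_bp = seq(1000L, by = 500L, length.out = m))
  co_iid$dosages <- D
  ph_iid <- estimate_pihat(co_iid)
  expect_lt(mean(ph_iid$pihat), 0.01)
  expect_lt(unname(quantile(ph_iid$pihat, 0.99)), 0.05)
})

test_that("prune_related removes the minimum necessary and is seeded", {
  ph0 <- data.frame(id1 = c("a", "b"), id2 = c("b", "c"),
                    pihat = c(0.1, 0.15))
  class(ph0) <- c("pihat_table", "data.frame")
  expect_setequal(prune_related(ph0, 0.2, seed = 1), c("a", "b", "c"))

  ph1 <- data.frame(id1 = "a", id2 = "b", pihat = 0.99)
  class(ph1) <- c("pihat_table", "data.frame")
  kept <- prune_related(ph1, 0.2, seed = 3, sample_ids = c("a", "b", "c"))
  expect_length(kept, 2)
  expect_true("c" %in% kept)
  expect_identical(kept, prune_related(ph1, 0.2, seed = 3,
                                       sample_ids = c("a", "b", "c")))

  # 3-clique: exactly one member retained (minimal-removal count)
  cl <- expand.grid(id1 = c("x", "y", "z"), id2 = c("x", "y", "z"),
                    stringsAsFactors = FALSE)
  cl <- cl[cl$id1 < cl$id2, ]
  cl$pihat <- 0.5
  class(cl) <- c("pihat_table", "data.frame")
  for (s in 1:5) {
    kept <- prune_related(cl, 0.2, seed = s)
    expect_length(kept, 1)   # same count as exhaustive minimal removal
  }
})

test_that("post-condition: no retained pair exceeds the threshold", {
  fx <- rel_fixture()
  ph <- estimate_pihat(fx$cohort, fx$pruned)
  kept <- prune_related(ph, 0.2, seed = 42,
                        sample_ids = fx$cohort$sample_ids)
  remaining <- ph[ph$id1 %in% kept & ph$id2 %in% kept, ]
  expect_true(all(remaining$pihat <= 0.2))
  expect_lt(length(kept), length(fx$cohort$sample_ids))
})
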