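test_that("size factors: identical columns give unit factors, doubling doubles", {
  counts <- matrix(rpois(200, 50) + 1, ncol = 4)
  colnames(counts) <- paste0("s", 1:4)
  same <- counts[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(size_factors(same)), rep(1, 4))
  doubled <- counts
  doubled[, 2] <- 2L * doubled[, 2]
  s <- size_factors(doubled)
  s_ref <- size_factors(counts)
  # before the geometric-mean rescale the doubled sample's factor is 2x;
  # the ratio to the undoubled fit is invariant to the rescale
  expect_equal(unname(s[2] / s[1]), unname(2 * s_ref[2] / s_ref[1]),
               tolerance = 1e-12)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)
})

test_that("size factors match the independent median-of-ratios oracle", {
  set.seed(42)
  for (rep in 1:5) {
    counts <- matrix(rnbinom(200, mu = 80, size = 5), ncol = 4)
    colnames(counts) <- paste0("s", 1:4)
    expect_equal(unname(size_factors(counts)), oracle_size_factors(counts),
                 tolerance = 1e-12)
  }
})

test_that("size factors fall back to total counts when no gene is ubiquitous", {
  counts <- rbind(c(10L, 0L, 5L, 2L), c(0L, 8L, 1L, 3L))
  colnames(counts) <- paste0("s", 1:4)
  expect_warning(s <- size_factors(counts), "total-count")
  expect_equal(unname(s), unname(colSums(counts) / exp(mean(log(colSums(counts))))))
})

test_that("per-gene dispersion is near zero for Poisson counts", {
  set.seed(7)
  counts <- matrix(rpois(100 * 50, 100), nrow = 100)
  colnames(counts) <- paste0("s", 1:50)
  de <- estimate_dispersion(counts, method = "per-gene")
  # equidispersed data: the moment estimate should be tiny vs real
  # biological dispersions (floored from below at 1e-8)
  expect_gte(mean(de$alpha < 0.01), 0.9)
  expect_true(all(de$alpha >= de$floor))
})

test_that("per-gene dispersion recovers a true NB alpha of 0.2", {
  set.seed(8)
  counts <- matrix(rnbinom(500 * 50, mu = 200, size = 1 / 0.2), nrow = 500)
  colnames(counts) <- paste0("s", 1:50)
  de <- estimate_dispersion(counts, method = "per-gene")
  expect_gt(median(de$alpha), 0.1)
  expect_lt(median(de$alpha), 0.4)
  # trend and pooled methods agree on the centre at constant truth
  tr <- estimate_dispersion(counts, method = "trend")
  expect_gt(median(tr$alpha), 0.1)
  expect_lt(median(tr$alpha), 0.4)
})

test_that("constant and zero genes get the dispersion floor, flagged", {
  # identical samples so normalization is exactly neutral
  counts <- matrix(rep(c(5L, 0L, 50L), 6), nrow = 3,
                   dimnames = list(c("const", "zero", "ok"), paste0("s", 1:6)))
  de <- estimate_dispersion(counts, method = "per-gene")
  expect_equal(unname(de$alpha["zero"]), de$floor)
  expect_equal(unname(de$alpha["const"]), de$floor)
  expect_true(de$flagged["zero"])
  expect_true(de$flagged["const"])   # zero variance
})

test_that("identical groups give log2FC 0 and p 1", {
  set.seed(3)
  base <- matrix(rnbinom(300, mu = 100, size = 10), ncol = 3)
  counts <- cbind(base, base)
  colnames(counts) <- paste0("s", 1:6)
  de <- nb_wald_contrast(counts, de_contrast("self", paste0("s", 1:3),
                                             paste0("s", 4:6)))
  expect_true(all(de$log2FC == 0))
  expect_true(all(de$pvalue == 1))
})

test_that("all-zero genes get log2FC 0 and p 1", {
  set.seed(3)
  counts <- matrix(rnbinom(600, mu = 100, size = 10), ncol = 6)
  counts[5, ] <- 0L
  rownames(counts) <- paste0("g", 1:100)
  colnames(counts) <- paste0("s", 1:6)
  de <- nb_wald_contrast(counts, de_contrast("c", paste0("s", 1:3),
                                             paste0("s", 4:6)))
  expect_equal(de$log2FC[5], 0)
  expect_equal(de$pvalue[5], 1)
  expect_false(de$tested[5])
})

test_that("swapping the groups negates log2FC and preserves p-values", {
  b <- simulate_ripseq_counts(sim_config(n_genes = 300, seed = 17))
  a_ids <- b$samples$sample_id[b$samples$fraction == "Input" &
                               b$samples$treatment == "miR"]
  b_ids <- b$samples$sample_id[b$samples$fraction == "Input" &
                               b$samples$treatment == "scramble"]
  de_ab <- nb_wald_contrast(b$counts, de_contrast("ab", a_ids, b_ids))
  de_ba <- nb_wald_contrast(b$counts, de_contrast("ba", b_ids, a_ids))
  expect_equal(de_ba$log2FC, -de_ab$log2FC)
  expect_equal(de_ba$pvalue, de_ab$pvalue)
})

test_that("log2FC is invariant to rescaling one sample's library size", {
  set.seed(9)
  counts <- matrix(rnbinom(400 * 6, mu = 5e4, size = 20), ncol = 6)
  rownames(counts) <- paste0("g", 1:400)
  colnames(counts) <- paste0("s", 1:6)
  ct <- de_contrast("c", paste0("s", 1:3), paste0("s", 4:6))
  de1 <- nb_wald_contrast(counts, ct)
  scaled <- counts
  scaled[, 2] <- as.integer(round(2 * scaled[, 2]))
  de2 <- nb_wald_contrast(scaled, ct)
  hi <- de1$baseMean_a > 1e4 & de1$baseMean_b > 1e4
  # integer rounding of the scaled column perturbs counts by < 1 each;
  # on abundant genes the fold changes agree essentially exactly
  expect_lt(max(abs(de1$log2FC[hi] - de2$log2FC[hi])), 1e-3)
  # with an exact scaling (no rounding) invariance is at numerical precision
  cf <- counts
  storage.mode(cf) <- "double"
  cf[, 2] <- 2 * cf[, 2]
  de3 <- nb_wald_contrast(cf, ct)
  expect_lt(max(abs(de1$log2FC[hi] - de3$log2FC[hi])), 1e-6)
})

test_that("a planted threefold gene at high abundance is detected", {
  set.seed(31)
  hits <- 0; lfcs <- numeric(0)
  for (r in 1:30) {
    counts <- matrix(rnbinom(300 * 6, mu = 300, size = 1 / 0.02), ncol = 6)
    counts[1, 1:3] <- rnbinom(3, mu = 900, size = 1 / 0.02)
    rownames(counts) <- paste0("g", 1:300)
    colnames(counts) <- paste0("s", 1:6)
    de <- nb_wald_contrast(counts, de_contrast("c", paste0("s", 1:3),
                                               paste0("s", 4:6)))
    if (de$pvalue[1] < 0.05 && de$log2FC[1] > 0) hits <- hits + 1
    lfcs <- c(lfcs, de$log2FC[1])
  }
  expect_gte(hits / 30, 0.9)
  expect_lt(abs(mean(lfcs) - log2(3)), 0.5)
})

test_that("contrast construction rejects undersized or overlapping groups", {
  expect_error(de_contrast("x", "s1", c("s2", "s3")), ">= 2 samples")
  expect_error(de_contrast("x", c("s1", "s2"), c("s2", "s3")), "disjoint")
  counts <- matrix(1L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_error(nb_wald_contrast(counts, de_contrast("x", c("s1", "s2"),
                                                    c("s3", "zz"))),
               "zz")
})

test_that("PCA screen flags a permuted sample and respects symmetry", {
  set.seed(12)
  base <- rnbinom(600, mu = 200, size = 5) + 1L
  counts <- cbind(base, base, base, sample(base))
  rownames(counts) <- paste0("g", 1:600)
  colnames(counts) <- paste0("s", 1:4)
  samples <- data.frame(sample_id = paste0("s", 1:4), fraction = "Input",
                        treatment = "miR", replicate = 1:4,
                        stringsAsFactors = FALSE)
  scr <- pca_outlier_screen(counts, samples)
  expect_equal(scr$flagged, "s4")
  # permutation symmetry: shuffling sample order flags the same sample
  perm <- c(3, 1, 4, 2)
  scr2 <- pca_outlier_screen(counts[, perm], samples[perm, ])
  expect_equal(scr2$flagged, "s4")
  # all-identical samples: nothing to flag
  same <- counts[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  scr3 <- pca_outlier_screen(same, samples)
  expect_length(scr3$flagged, 0)
})

test_that("PCA screen reduces the PC count when samples are few", {
  counts <- matrix(rpois(30, 100) + 1L, ncol = 3)
  rownames(counts) <- paste0("g", 1:10)
  colnames(counts) <- paste0("s", 1:3)
  samples <- data.frame(sample_id = paste0("s", 1:3), fraction = "Input",
                        treatment = "miR", replicate = 1:3,
                        stringsAsFactors = FALSE)
  expect_warning(scr <- pca_outlier_screen(counts, samples, n_pcs = 5),
                 "reducing")
  expect_error(pca_outlier_screen(counts[, 1:2], samples[1:2, ]), "3 samples")
})
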