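test_that("LD pruning removes duplicates and leaves independent SNPs alone", {
  set.seed(22)
  g <- sapply(runif(20, 0.2, 0.8), function(p) rbinom(40, 2, p))
  dup <- cbind(g[, 1:10], g[, 1], g[, 11:20])       # column 11 duplicates 1
  ds <- make_dataset(dup)
  kept <- ld_prune(ds, prune_params(window_snps = 15, step_snps = 3,
                                    r2_max = 0.5))
  expect_equal(sum(c(1, 11) %in% kept), 1)          # exactly one of the pair
  # independent markers: nothing pruned
  ds2 <- make_dataset(g)
  r2max <- 0
  for (i in 1:19) for (j in (i + 1):20)
    r2max <- max(r2max, suppressWarnings(genotype_r2(ds2, i, j)), na.rm = TRUE)
  kept2 <- ld_prune(ds2, prune_params(r2_max = max(0.9, r2max + 0.01)))
  expect_equal(kept2, 1:20)
})

test_that("pruned sets satisfy the post-condition by enumeration", {
  ds <- random_dataset(30, 100, missing = 0.02, seed = 23)
  prm <- prune_params(window_snps = 20, step_snps = 5, r2_max = 0.4)
  kept <- ld_prune(ds, prm)
  # within any map window, no retained pair exceeds r2_max
  for (st in seq(1, nrow(ds$snps), by = prm$step_snps)) {
    win <- intersect(st:min(st + prm$window_snps - 1, nrow(ds$snps)), kept)
    if (length(win) < 2) next
    for (i in seq_along(win)[-1]) for (j in seq_len(i - 1)) {
      r2 <- suppressWarnings(genotype_r2(ds, win[j], win[i]))
      if (!is.na(r2)) expect_lte(r2, prm$r2_max)
    }
  }
})

test_that("IBS matrix matches per-pair computation, symmetric, unit diagonal", {
  ds <- random_dataset(12, 80, missing = 0.05, seed = 24)
  ibs <- ibs_matrix(ds)
  expect_equal(ibs, t(ibs))
  expect_equal(unname(diag(ibs)), rep(1, 12))
  g <- ds$calls
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    i <- pair[1]; j <- pair[2]
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    expect_equal(ibs[i, j], mean((2 - abs(g[i, ok] - g[j, ok])) / 2),
                 tolerance = 1e-12)
  }
  # identical samples -> 1; opposite homozygotes -> 0
  gg <- rbind(rep(0L, 10), rep(0L, 10), rep(2L, 10))
  ibs2 <- ibs_matrix(make_dataset(gg))
  expect_equal(ibs2[1, 2], 1)
  expect_equal(ibs2[1, 3], 0)
})

test_that("relatedness removal keeps one of each clone pair, deterministically", {
  set.seed(25)
  g <- sapply(runif(60, 0.2, 0.8), function(p) rbinom(3, 2, p))
  trio <- rbind(g[1, ], g[1, ], g[3, ])             # two clones + outlier
  trio[3, ] <- rbinom(60, 2, 0.5)
  ds <- make_dataset(trio)
  red <- remove_related(ds, 0.9)
  expect_equal(nrow(red$samples), 2)
  expect_true("ind003" %in% red$samples$sample_id)
  # clone tie on call rate: lexicographically larger id removed
  expect_true("ind001" %in% red$samples$sample_id)
  # nothing above cutoff: unchanged
  ds2 <- random_dataset(8, 100, missing = 0, seed = 26)
  red2 <- remove_related(ds2, 0.999)
  expect_equal(red2$samples, ds2$samples)
})

test_that("PCA matches a dense eigendecomposition and separates demes", {
  ds <- random_dataset(20, 100, missing = 0.03, seed = 27)
  res <- pca_genotypes(ds, k = 5)
  # oracle: full eigendecomposition of the scaled covariance
  g <- ds$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  use <- p > 0 & p < 1
  g <- g[, use, drop = FALSE]; p <- p[use]
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- 2 * p[j]
  z <- sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  ev <- eigen(z %*% t(z) / (nrow(g) - 1), symmetric = TRUE)$values
  expect_equal(res$eigenvalues, ev[1:5], tolerance = 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-8))
  expect_true(all(res$variance_fraction >= 0) &&
                sum(res$variance_fraction) <= 1 + 1e-8)
  # identical samples -> identical coordinates
  dup <- make_dataset(rbind(ds$calls[1, ], ds$calls[1, ], ds$calls[2:6, ]),
                      bp = ds$snps$bp_pos)
  cd <- pca_genotypes(dup, 2)$coordinates
  expect_equal(as.numeric(cd[1, c("PC1", "PC2")]),
               as.numeric(cd[2, c("PC1", "PC2")]), tolerance = 1e-8)
  expect_error(pca_genotypes(ds, k = 20), "n_samples")

  # two drift-diverged populations separate on PC1
  sim <- wf_small()
  qc <- apply_qc(sim$dataset, qc_params())
  pr <- pca_genotypes(subset_dataset(qc$dataset,
                                     snps = ld_prune(qc$dataset)), k = 2)
  pc1 <- pr$coordinates$PC1
  lab <- pr$coordinates$population
  between <- abs(mean(pc1[lab == "A"]) - mean(pc1[lab == "B"]))
  within <- mean(c(sd(pc1[lab == "A"]), sd(pc1[lab == "B"])))
  expect_gt(between / within, 1)
})
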