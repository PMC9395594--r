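test_that("F_HOM matches a direct recomputation and has the right signs", {
  set.seed(8)
  ds <- make_dataset(rbind(c(0L, 2L, 0L, 2L),
                           c(1L, 1L, 1L, 1L),
                           c(0L, 1L, 2L, NA),
                           c(2L, 0L, 1L, 0L),
                           c(1L, 2L, 0L, 1L)))
  fh <- compute_fhom(ds)
  # brute-force per the formula, cohort frequencies with n/(n-1) correction
  g <- ds$calls
  for (i in 1:5) {
    obs_j <- which(!is.na(g[i, ]))
    o <- sum(g[i, obs_j] != 1L)
    e <- sum(vapply(obs_j, function(j) {
      gj <- g[!is.na(g[, j]), j]
      nj <- 2 * length(gj)
      pj <- sum(gj) / nj
      1 - 2 * pj * (1 - pj) * nj / (nj - 1)
    }, numeric(1)))
    expect_equal(fh$f_hom[i], (o - e) / (length(obs_j) - e), tolerance = 1e-12)
  }
  expect_equal(fh$f_hom[1], 1)          # fully homozygous sample
  expect_lt(fh$f_hom[2], 0)             # heterozygous at every SNP
})

test_that("F_ROH is segment length over the autosomal denominator", {
  samples <- data.frame(sample_id = c("a", "b"), population = "P")
  segs <- data.frame(sample_id = "a", population = "P", chrom = "1",
                     start_bp = 1e6, end_bp = 246.071e6, n_snps = 1000L,
                     length_bp = 245.071e6)
  attr(segs, "samples") <- samples
  fr <- compute_froh(segs, l_auto = 2450.71e6)
  expect_equal(fr$f_roh[fr$sample_id == "a"], 0.1)
  expect_equal(fr$f_roh[fr$sample_id == "b"], 0)
})

test_that("class-wise and chromosome-wise F_ROH partition the total", {
  sim <- wf_small()
  rs <- detect_roh(sim$dataset, roh_params(window_snps = 15,
                                           min_snps_in_roh = 15,
                                           min_length_bp = 5e5,
                                           max_missing_in_roh = 2))
  expect_gt(nrow(rs), 0)
  la <- l_auto_bp(sim$dataset)
  total <- compute_froh(rs, la)
  fc <- froh_by_class(rs, la, length_class_scheme(c(0.5, 1, 5, 10)))
  cls_cols <- setdiff(names(fc$per_sample),
                      c("sample_id", "population", "total"))
  expect_equal(rowSums(fc$per_sample[, cls_cols, drop = FALSE]),
               fc$per_sample$total, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fc$per_sample$total, total$f_roh, tolerance = 1e-12)
  # chromosome-wise bp totals partition L_ROH exactly
  fchr <- froh_by_chromosome(rs, sim$dataset)
  spans <- rohscape:::chrom_spans(sim$dataset$snps)
  bp_by_chr <- sweep(as.matrix(fchr[, spans$chrom, drop = FALSE]), 2,
                     spans$last_bp - spans$first_bp, "*")
  expect_equal(rowSums(bp_by_chr), total$l_roh_bp, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("single-segment class assignment and chromosome F_ROH extremes", {
  samples <- data.frame(sample_id = "a", population = "P")
  segs <- data.frame(sample_id = "a", population = "P", chrom = "1",
                     start_bp = 2e6, end_bp = 8e6, n_snps = 80L,
                     length_bp = 6e6)
  attr(segs, "samples") <- samples
  fc <- froh_by_class(segs, l_auto = 1e8)
  expect_equal(fc$per_sample[["5-10Mb"]], 6e6 / 1e8)
  expect_equal(fc$per_sample[["1-5Mb"]], 0)
  # a segment spanning the whole chromosome span gives chromosome F_ROH 1
  bp <- seq(2e6, 8e6, length.out = 50)
  ds <- make_dataset(matrix(0L, 1, 50), bp = bp)
  segs$sample_id <- ds$samples$sample_id[1]
  segs$start_bp <- bp[1]; segs$end_bp <- bp[50]; segs$length_bp <- bp[50] - bp[1]
  fchr <- froh_by_chromosome(segs, ds)
  expect_equal(fchr[["1"]], 1)
})

test_that("F_ROH rank-orders the mating designs by expected inbreeding", {
  base <- founders_base()
  la <- l_auto_bp(base)
  mean_froh <- vapply(c("selfing_like", "full_sib", "half_sib", "outbred"),
                      function(d) {
    off <- simulate_pedigree_inbreeding(base, d, 12, seed = 5)
    mean(compute_froh(detect_roh(off$dataset), la)$f_roh)
  }, numeric(1))
  expect_true(all(diff(mean_froh) < 0))
})

test_that("F_ROH/F_HOM correlation behaves on constructed groups", {
  tab <- data.frame(population = rep("P", 4),
                    f_roh = c(0.1, 0.2, 0.3, 0.4),
                    f_hom = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(froh_fhom_correlation(tab)$correlation, 1)
  tab$f_hom <- rev(tab$f_hom)
  expect_equal(froh_fhom_correlation(tab)$correlation, -1)
  tab$f_hom <- 0.2
  expect_true(is.na(froh_fhom_correlation(tab)$correlation))
  # mixed inbred/outbred cohort: strong positive correlation
  base <- founders_base()
  fs <- simulate_pedigree_inbreeding(base, "full_sib", 12, seed = 9)
  ob <- simulate_pedigree_inbreeding(base, "outbred", 12, seed = 10)
  mix <- genotype_dataset(base$snps,
                          rbind(fs$dataset$samples, ob$dataset$samples),
                          rbind(fs$dataset$calls, ob$dataset$calls))
  mix$samples$population <- "MIX"
  mix <- genotype_dataset(mix$snps, mix$samples, mix$calls)
  inb <- inbreeding_table(mix, detect_roh(mix))
  r <- froh_fhom_correlation(inb)$correlation
  expect_gt(r, 0.5)
})
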