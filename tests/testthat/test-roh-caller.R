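test_that("degenerate genotype rows give the expected calls", {
  bp <- seq(1e6, 11e6, length.out = 200)
  snps <- make_dataset(matrix(0L, 1, 200), bp = bp)$snps
  prm <- roh_params()
  # all-heterozygous individual: nothing
  expect_equal(nrow(detect_roh_individual(rep(1L, 200), snps, prm)), 0)
  # fully homozygous individual: one segment spanning first to last SNP
  seg <- detect_roh_individual(rep(0L, 200), snps, prm)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, bp[1])
  expect_equal(seg$end_bp, bp[200])
  expect_equal(seg$n_snps, 200L)
  # chromosome shorter than the window: no calls, no error
  expect_equal(nrow(detect_roh_individual(rep(0L, 10), snps[1:10, ],
                                          prm)), 0)
  # unsorted map errors
  snps_bad <- snps
  snps_bad$bp_pos[1:2] <- snps_bad$bp_pos[2:1]
  expect_error(genotype_dataset(snps_bad, data.frame(sample_id = "a",
                                                     population = "p"),
                                matrix(0L, 1, 200)), "sorted")
})

test_that("two-phase caller equals the brute-force scanner on random rows", {
  set.seed(14)
  prm <- roh_params(window_snps = 10, min_snps_in_roh = 10,
                    min_length_bp = 1e5, max_missing_in_roh = 1e9,
                    max_het_in_roh = 0, max_gap_bp = 5e5)
  for (rep in 1:25) {
    m <- sample(100:500, 1)
    bp <- sort(sample.int(2e7, m))
    g <- sample(c(0L, 0L, 2L, 1L, NA), m, replace = TRUE)
    snps <- make_dataset(matrix(g, 1), bp = bp)$snps
    got <- detect_roh_individual(g, snps, prm)
    want <- brute_roh(g, bp, prm$min_snps_in_roh, prm$min_length_bp,
                      prm$max_gap_bp)
    expect_equal(got$start_bp, want$start)
    expect_equal(got$end_bp, want$end)
    expect_equal(got$n_snps, as.integer(want$n))
  }
})

test_that("tightening thresholds is monotone and segments never overlap", {
  set.seed(15)
  m <- 600
  bp <- sort(sample.int(3e7, m))
  g <- ifelse(runif(m) < 0.85, sample(c(0L, 2L), m, replace = TRUE), 1L)
  snps <- make_dataset(matrix(g, 1), bp = bp)$snps
  base <- roh_params(window_snps = 10, min_snps_in_roh = 10,
                     min_length_bp = 1e5, max_het_in_roh = 0)
  n_base <- nrow(detect_roh_individual(g, snps, base))
  stricter_len <- base; stricter_len$min_length_bp <- 1e6
  stricter_n <- base; stricter_n$min_snps_in_roh <- 30
  expect_lte(nrow(detect_roh_individual(g, snps, stricter_len)), n_base)
  expect_lte(nrow(detect_roh_individual(g, snps, stricter_n)), n_base)
  # note: no monotonicity claim for max_het_in_roh -- loosening it merges
  # flagged stretches into runs that can then violate the per-run het cap
  segs <- detect_roh_individual(g, snps, base)
  if (nrow(segs) > 1)
    expect_true(all(segs$start_bp[-1] > segs$end_bp[-nrow(segs)]))
})

test_that("cohort detection groups per-individual calls with metadata", {
  bp <- seq(1e6, 11e6, length.out = 200)
  calls <- rbind(rep(0L, 200), rep(0L, 200), rep(1L, 200))
  ds <- make_dataset(calls, bp = bp, pops = c("P1", "P1", "P2"))
  rs <- detect_roh(ds)
  expect_s3_class(rs, "roh_set")
  expect_equal(nrow(rs), 2)
  expect_equal(unique(rs$population), "P1")
  # identical individuals get identical segments
  expect_equal(rs[rs$sample_id == "ind001", -1], rs[rs$sample_id == "ind002", -1],
               ignore_attr = TRUE)
})

test_that("length classes are left-closed and counts are conserved", {
  mk_seg <- function(len_mb, pop) data.frame(
    sample_id = "x", population = pop, chrom = "1", start_bp = 1e6,
    end_bp = 1e6 + len_mb * 1e6, n_snps = 60L, length_bp = len_mb * 1e6)
  segs <- do.call(rbind, list(mk_seg(5, "A"), mk_seg(2, "A"), mk_seg(12, "B"),
                              mk_seg(45, "B"), mk_seg(20, "A")))
  tab <- classify_lengths(segs)
  expect_equal(tab$A[tab$class == "1-5Mb"], 1)       # the 2 Mb segment
  expect_equal(tab$A[tab$class == "5-10Mb"], 1)      # exactly 5.0 Mb
  expect_equal(tab$A[tab$class == "20-40Mb"], 1)     # exactly 20 Mb
  expect_equal(tab$B[tab$class == ">40Mb"], 1)
  expect_equal(tab$Total[tab$class == "Total"], nrow(segs))
  empty <- classify_lengths(segs[0, ])
  expect_true(all(empty$Total == 0))
})

test_that("summaries average over all individuals including ROH-free ones", {
  bp <- seq(1e6, 3e6, length.out = 120)
  calls <- rbind(rep(0L, 120), rep(1L, 120))
  ds <- make_dataset(calls, bp = bp, pops = c("P", "P"))
  rs <- detect_roh(ds)
  s <- roh_summary(rs, ds)
  expect_equal(s$mean_roh_per_individual[s$population == "P"], 0.5)
  expect_equal(s$mean_length_mb[s$population == "P"], 2.0)
  expect_equal(s$n_with_roh[s$population == "P"], 1)
})

test_that("chromosome coverage equals an interval-accumulation oracle", {
  sim <- wf_small()
  rs <- detect_roh(sim$dataset, roh_params(window_snps = 15,
                                           min_snps_in_roh = 15,
                                           min_length_bp = 5e5,
                                           max_missing_in_roh = 2))
  tab <- chrom_counts_and_coverage(rs, sim$dataset, by_population = FALSE)
  spans <- rohscape:::chrom_spans(sim$dataset$snps)
  n <- nrow(sim$dataset$samples)
  for (k in seq_len(nrow(spans))) {
    s <- rs[as.character(rs$chrom) == spans$chrom[k], ]
    expect_equal(tab$n_segments[k], nrow(s))
    expect_equal(tab$coverage[k],
                 sum(s$length_bp) / ((spans$last_bp[k] - spans$first_bp[k]) * n))
  }
  # no segments on a chromosome -> zero count and coverage
  none <- rs[0, ]
  attr(none, "samples") <- sim$dataset$samples
  tab0 <- chrom_counts_and_coverage(none, sim$dataset, by_population = FALSE)
  expect_true(all(tab0$n_segments == 0) && all(tab0$coverage == 0))
})

test_that("reported segment lengths round half-up to 2 decimals", {
  expect_equal(segment_length_mb(39467151, 137516937), 98.05)
  expect_equal(segment_length_mb(60187788, 67883046), 7.70)
  expect_equal(segment_length_mb(0, 1e6), 1.00)
  expect_equal(segment_length_mb(0, 1005000), 1.01)  # half rounds up
})
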