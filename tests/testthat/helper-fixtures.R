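# Fixture builders and independent oracles shared across test files.

# minimal dataset from a dosage matrix; evenly spaced SNPs on one chromosome
# unless chrom/bp given
make_dataset <- function(calls, bp = NULL, chrom = NULL, pops = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(bp)) bp <- seq(1e6, by = 1e5, length.out = m)
  if (is.null(chrom)) chrom <- rep("1", m)
  snps <- data.frame(chrom = chrom, snp_id = sprintf("s%04d", seq_len(m)),
                     genetic_pos = bp / 1e6, bp_pos = bp,
                     allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  n <- nrow(calls)
  if (is.null(pops)) pops <- rep("POP", n)
  samples <- data.frame(sample_id = sprintf("ind%03d", seq_len(n)),
                        population = pops, stringsAsFactors = FALSE)
  genotype_dataset(snps, samples, calls)
}

random_dataset <- function(n, m, missing = 0.02, maf_lo = 0.1, seed = 1,
                           n_chrom = 1) {
  set.seed(seed)
  p <- runif(m, maf_lo, 1 - maf_lo)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (missing > 0) {
    mask <- runif(n * m) < missing
    calls[mask] <- NA_integer_
  }
  chrom <- as.character(rep(seq_len(n_chrom), each = ceiling(m / n_chrom))[1:m])
  bp <- unlist(lapply(table(factor(chrom, levels = unique(chrom))),
                      function(k) sort(sample.int(5e7, k))))
  make_dataset(calls, bp = bp, chrom = chrom)
}

# --- independent ROH oracle -------------------------------------------------
# Maximal het-free stretches, split at bp gaps > max_gap, kept when they meet
# the SNP-count and length minima. Valid comparison domain for the
# two-phase caller: max_het = 0, max_missing not binding, window <= min_snps,
# hit fraction < 1/window.
brute_roh <- function(g, bp, min_snps, min_len_bp, max_gap_bp) {
  het <- !is.na(g) & g == 1L
  segs <- list()
  idx <- seq_along(g)
  stretch_id <- cumsum(het)
  for (pieces in split(idx[!het], stretch_id[!het])) {
    if (!length(pieces)) next
    gap_cut <- cumsum(c(0, diff(bp[pieces]) > max_gap_bp))
    for (piece in split(pieces, gap_cut)) {
      if (length(piece) >= min_snps &&
          bp[piece[length(piece)]] - bp[piece[1]] >= min_len_bp)
        segs[[length(segs) + 1]] <- c(start = bp[piece[1]],
                                      end = bp[piece[length(piece)]],
                                      n = length(piece))
    }
  }
  if (!length(segs))
    return(data.frame(start = numeric(0), end = numeric(0), n = integer(0)))
  as.data.frame(do.call(rbind, segs))
}

# --- independent HWE oracle -------------------------------------------------
# Direct enumeration of the conditional heterozygote-count distribution via
# log-multinomial coefficients.
hwe_enum_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het
  n_b <- 2 * n_hom_alt + n_het
  n_rare <- min(n_a, n_b)
  if (n_rare == 0) return(1.0)
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_rare - h) / 2
    nbb <- n - h - naa
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(n_rare) -
                      lfactorial(2 * n - n_rare))
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# --- cached expensive simulations ------------------------------------------
fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- builder()
  fixture_cache[[name]]
}

# unrelated, heterozygous founder panel for pedigree designs: 40 founders,
# ~2800 SNPs on 4 x 60 Mb autosomes (about 12 SNPs/Mb). Ne 500 over 20
# generations keeps expected background autozygosity near
# 1 - (1 - 1/1000)^20 ~ 2%, so pedigree designs dominate the offspring's
# realized inbreeding.
founders_base <- function() cached("founders_base", function() {
  simulate_wright_fisher(sim_params(
    n_autosomes = 4, chrom_length_bp = 6e7, n_snps = 3000,
    sample_sizes = c(BASE = 40),
    ne_trajectory = data.frame(generation = 1, ne = 500),
    n_generations = 20, missing_rate = 0, seed = 11))$dataset
})

# small two-population panel for QC / structure / pipeline tests
wf_small <- function() cached("wf_small", function() {
  simulate_wright_fisher(sim_params(
    n_autosomes = 2, chrom_length_bp = 6e7, n_snps = 900,
    sample_sizes = c(A = 15, B = 15),
    ne_trajectory = data.frame(generation = 1, ne = 60),
    n_generations = 80, missing_rate = 0.01, seed = 7))
})
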