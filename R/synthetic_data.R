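#' Simulation parameters
#'
#' Defaults emulate a scaled-down SNP50-style panel: a few autosomes of
#' 50-100 Mb, a few thousand mapped SNPs, several populations of 20-55
#' individuals with realistic LD decay (1 cM/Mb), sparse missing calls and a
#' constant diploid Ne of 100 over 200 non-overlapping generations. The Ne
#' trajectory is a step function: `ne_trajectory$ne[k]` holds from generation
#' `ne_trajectory$generation[k]` until the next breakpoint.
#'
#' @param n_autosomes number of simulated autosomes.
#' @param chrom_length_bp length of each autosome in bp.
#' @param n_snps total number of SNPs across autosomes.
#' @param ne_trajectory data.frame with columns `generation` (1-based start
#'   generation) and `ne` (diploid size, >= 2).
#' @param n_generations number of generations to simulate.
#' @param recomb_rate map rate in cM per Mb.
#' @param mutation_rate per-site per-generation flip probability.
#' @param sample_sizes named vector of per-population sample sizes; each
#'   population descends independently from a shared founder allele-frequency
#'   spectrum, so populations diverge by drift alone.
#' @param missing_rate fraction of genotype calls masked missing.
#' @param seed integer seed; simulations are deterministic given the seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_autosomes = 4, chrom_length_bp = 8e7, n_snps = 3000,
                       ne_trajectory = data.frame(generation = 1, ne = 100),
                       n_generations = 200, recomb_rate = 1.0,
                       mutation_rate = 1e-8,
                       sample_sizes = c(P1 = 24, P2 = 28, P3 = 35),
                       missing_rate = 0.01, seed = 1) {
  stopifnot(n_autosomes >= 1, chrom_length_bp > 0, n_snps >= n_autosomes,
            n_generations >= 1, recomb_rate >= 0, mutation_rate >= 0,
            all(sample_sizes > 0), missing_rate >= 0, missing_rate < 1,
            all(ne_trajectory$ne >= 2), nrow(ne_trajectory) >= 1)
  if (is.null(names(sample_sizes)))
    names(sample_sizes) <- paste0("P", seq_along(sample_sizes))
  structure(list(n_autosomes = n_autosomes, chrom_length_bp = chrom_length_bp,
                 n_snps = n_snps, ne_trajectory = ne_trajectory,
                 n_generations = n_generations, recomb_rate = recomb_rate,
                 mutation_rate = mutation_rate, sample_sizes = sample_sizes,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_params")
}

# per-SNP gamete switch probabilities: 0.5 at each chromosome start
# (independent assortment), Haldane's map function within chromosomes
switch_probs <- function(snps) {
  r <- numeric(nrow(snps))
  for (idx in chrom_blocks(snps)) {
    r[idx[1]] <- 0.5
    if (length(idx) > 1) {
      d <- diff(snps$genetic_pos[idx])  # cM
      r[idx[-1]] <- 0.5 * (1 - exp(-2 * d / 100))
    }
  }
  r
}

# one gamete per row: recombinant mosaic of each parent's two haplotypes
make_gametes <- function(haps, parents, rec, mutation_rate) {
  ng <- length(parents)
  m <- ncol(haps)
  x <- matrix(stats::runif(ng * m) < rep(rec, each = ng), ng, m)
  chooser <- t(apply(x, 1, cumsum)) %% 2
  g <- haps[2L * parents - 1L, , drop = FALSE]
  a2 <- haps[2L * parents, , drop = FALSE]
  g[chooser == 1] <- a2[chooser == 1]
  if (mutation_rate > 0) {
    nm <- stats::rbinom(1, ng * m, mutation_rate)
    if (nm > 0) {
      pos <- sample.int(ng * m, nm)
      g[pos] <- 1L - g[pos]
    }
  }
  g
}

# diploid size per generation from the step trajectory
ne_per_generation <- function(traj, n_generations) {
  traj <- traj[order(traj$generation), , drop = FALSE]
  f <- stats::stepfun(traj$generation, c(traj$ne[1], traj$ne))
  pmax(2, round(f(seq_len(n_generations))))
}

build_map <- function(params) {
  per_chrom <- diff(round(seq(0, params$n_snps,
                              length.out = params$n_autosomes + 1)))
  snps <- do.call(rbind, lapply(seq_len(params$n_autosomes), function(ch) {
    bp <- sort(sample.int(params$chrom_length_bp, per_chrom[ch]))
    data.frame(chrom = as.character(ch),
               snp_id = sprintf("snp_%d_%06d", ch, seq_along(bp)),
               genetic_pos = bp / 1e6 * params$recomb_rate,
               bp_pos = bp, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE)
  }))
  rownames(snps) <- NULL
  snps
}

#' Forward-in-time Wright-Fisher genotype simulation
#'
#' Discrete non-overlapping generations; every gamete draws a parent
#' uniformly at random from the previous generation and recombines the
#' parent's two haplotypes with Haldane (no-interference) crossover
#' probabilities from the cM map; bi-allelic mutation flips alleles at
#' `mutation_rate`. Each named population evolves independently from a shared
#' founder allele-frequency spectrum (Uniform(0.05, 0.95) per SNP), then
#' `sample_sizes` individuals are drawn without replacement from the final
#' generation. SNPs monomorphic in the combined cohort are dropped and calls
#' are masked missing at `missing_rate`.
#'
#' @param params a [sim_params()] object.
#' @return List with `dataset` (a `genotype_dataset`) and `truth` (class
#'   `truth_record`: per-sample expected pedigree F of 0, the realized Ne per
#'   generation, no implanted islands).
#' @export
simulate_wright_fisher <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  snps <- build_map(params)
  rec <- switch_probs(snps)
  m <- nrow(snps)
  p0 <- stats::runif(m, 0.05, 0.95)
  sizes <- ne_per_generation(params$ne_trajectory, params$n_generations)

  pops <- names(params$sample_sizes)
  geno <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    n1 <- sizes[1]
    haps <- matrix(stats::rbinom(2L * n1 * m, 1L, rep(p0, each = 2L * n1)),
                   2L * n1, m)
    for (g in seq_len(params$n_generations)[-1]) {
      n_prev <- nrow(haps) / 2L
      n_next <- sizes[g]
      parents <- sample.int(n_prev, 2L * n_next, replace = TRUE)
      haps <- make_gametes(haps, parents, rec, params$mutation_rate)
    }
    n_final <- nrow(haps) / 2L
    n_take <- params$sample_sizes[k]
    if (n_take > n_final)
      stop(sprintf("population %s: requested %d samples but only %d individuals",
                   pops[k], n_take, n_final))
    ids <- sample.int(n_final, n_take)
    geno[[k]] <- haps[2L * ids - 1L, , drop = FALSE] +
      haps[2L * ids, , drop = FALSE]
  }
  calls <- do.call(rbind, geno)
  samples <- data.frame(
    sample_id = sprintf("%s_%03d",
                        rep(pops, params$sample_sizes),
                        unlist(lapply(params$sample_sizes, seq_len))),
    population = rep(pops, params$sample_sizes),
    stringsAsFactors = FALSE)

  freq <- colMeans(calls) / 2
  keep <- freq > 0 & freq < 1
  calls <- calls[, keep, drop = FALSE]
  snps <- snps[keep, , drop = FALSE]
  if (params$missing_rate > 0) {
    nmask <- stats::rbinom(1, length(calls), params$missing_rate)
    if (nmask > 0) calls[sample.int(length(calls), nmask)] <- NA_integer_
  }
  truth <- structure(list(
    expected_f = stats::setNames(rep(0, nrow(samples)), samples$sample_id),
    islands = empty_island_truth(),
    ne_log = data.frame(generation = seq_along(sizes), ne = sizes)),
    class = "truth_record")
  list(dataset = genotype_dataset(snps, samples, calls), truth = truth)
}

empty_island_truth <- function() {
  data.frame(chrom = character(0), start_bp = numeric(0),
             end_bp = numeric(0), carrier_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

# phase a genotype row into two haplotypes, random phase at heterozygotes
phase_random <- function(g) {
  m <- length(g)
  h1 <- integer(m); h2 <- integer(m)
  h1[g == 2L] <- 1L; h2[g == 2L] <- 1L
  het <- which(g == 1L)
  if (length(het)) {
    coin <- stats::runif(length(het)) < 0.5
    h1[het[coin]] <- 1L
    h2[het[!coin]] <- 1L
  }
  rbind(h1, h2)
}

drop_gamete <- function(haps2, rec) {
  x <- stats::runif(length(rec)) < rec
  chooser <- cumsum(x) %% 2
  ifelse(chooser == 0, haps2[1, ], haps2[2, ])
}

#' Simulate offspring of a fixed mating design
#'
#' Builds offspring genotypes by recombinant gamete-dropping from founder
#' genotypes through a small pedigree, giving cohorts with known expected
#' inbreeding: `full_sib` offspring of a full-sib mating (F = 0.25),
#' `half_sib` offspring of a half-sib mating (F = 0.125), `selfing_like`
#' offspring of two independent gametes from a single founder (F = 0.5), and
#' `outbred` offspring of two unrelated founders (F = 0). Founder genotypes
#' are phased with random phase at heterozygotes; founder sets rotate across
#' offspring so the cohort is not a single family.
#'
#' @param base a `genotype_dataset` of founders (>= 4 samples, no missing
#'   calls required; missing founder calls are imputed to homozygous
#'   reference before phasing).
#' @param design one of `"full_sib"`, `"half_sib"`, `"selfing_like"`,
#'   `"outbred"`.
#' @param n_offspring cohort size.
#' @param seed integer seed.
#' @return List with `dataset` (offspring cohort, population label equal to
#'   the design) and `truth` (expected pedigree F per offspring).
#' @export
simulate_pedigree_inbreeding <- function(base, design, n_offspring = 30,
                                         seed = 1) {
  designs <- c(full_sib = 0.25, half_sib = 0.125,
               selfing_like = 0.5, outbred = 0)
  if (!design %in% names(designs))
    stop("unknown design '", design, "'; use one of ",
         paste(names(designs), collapse = ", "))
  if (nrow(base$samples) < 4) stop("base must contain at least 4 founders")
  set.seed(seed)
  rec <- switch_probs(base$snps)
  m <- nrow(base$snps)
  g0 <- base$calls
  g0[is.na(g0)] <- 0L
  founder_haps <- lapply(seq_len(nrow(g0)), function(i) phase_random(g0[i, ]))
  nf <- length(founder_haps)

  child_of <- function(pa_haps, ma_haps)
    rbind(drop_gamete(pa_haps, rec), drop_gamete(ma_haps, rec))

  calls <- matrix(NA_integer_, n_offspring, m)
  for (o in seq_len(n_offspring)) {
    fs <- sample.int(nf, min(3L, nf))
    off <- switch(design,
      outbred = child_of(founder_haps[[fs[1]]], founder_haps[[fs[2]]]),
      selfing_like = child_of(founder_haps[[fs[1]]], founder_haps[[fs[1]]]),
      full_sib = {
        s1 <- child_of(founder_haps[[fs[1]]], founder_haps[[fs[2]]])
        s2 <- child_of(founder_haps[[fs[1]]], founder_haps[[fs[2]]])
        child_of(s1, s2)
      },
      half_sib = {
        s1 <- child_of(founder_haps[[fs[1]]], founder_haps[[fs[2]]])
        s2 <- child_of(founder_haps[[fs[1]]], founder_haps[[fs[3]]])
        child_of(s1, s2)
      })
    calls[o, ] <- off[1, ] + off[2, ]
  }
  samples <- data.frame(sample_id = sprintf("%s_%03d", design,
                                            seq_len(n_offspring)),
                        population = design, stringsAsFactors = FALSE)
  truth <- structure(list(
    expected_f = stats::setNames(rep(designs[[design]], n_offspring),
                                 samples$sample_id),
    islands = empty_island_truth(),
    ne_log = data.frame(generation = integer(0), ne = numeric(0))),
    class = "truth_record")
  list(dataset = genotype_dataset(base$snps, samples, calls), truth = truth)
}

#' Implant an autozygosity island
#'
#' Overwrites the genotypes of a uniformly chosen `ceiling(carrier_fraction
#' * n)` subset of samples with homozygous-reference calls (no missing) at
#' every SNP inside `start_bp`..`end_bp` on `chrom`, creating a known ROH
#' island for recovery tests.
#'
#' @param dataset a `genotype_dataset`.
#' @param chrom chromosome label.
#' @param start_bp,end_bp region bounds (inclusive, bp).
#' @param carrier_fraction fraction of samples carrying the island, in
#'   `(0, 1]`.
#' @param seed integer seed for the carrier draw.
#' @return List with `dataset` (modified) and `truth` (island region and
#'   carrier ids).
#' @export
implant_island <- function(dataset, chrom, start_bp, end_bp,
                           carrier_fraction, seed = 1) {
  stopifnot(carrier_fraction > 0, carrier_fraction <= 1)
  idx <- which(as.character(dataset$snps$chrom) == as.character(chrom) &
                 dataset$snps$bp_pos >= start_bp &
                 dataset$snps$bp_pos <= end_bp)
  if (!length(idx)) stop("island region contains no SNPs")
  set.seed(seed)
  n <- nrow(dataset$samples)
  n_car <- as.integer(ceiling(carrier_fraction * n))
  carriers <- sort(sample.int(n, n_car))
  dataset$calls[carriers, idx] <- 0L
  truth <- structure(list(
    expected_f = stats::setNames(rep(NA_real_, n), dataset$samples$sample_id),
    islands = data.frame(chrom = as.character(chrom), start_bp = start_bp,
                         end_bp = end_bp, carrier_fraction = carrier_fraction,
                         stringsAsFactors = FALSE),
    carriers = dataset$samples$sample_id[carriers],
    ne_log = data.frame(generation = integer(0), ne = numeric(0))),
    class = "truth_record")
  list(dataset = dataset, truth = truth)
}
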