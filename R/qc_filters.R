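#' Quality-control parameters
#'
#' Defaults follow common medium-density SNP-array QC for livestock panels:
#' markers are dropped when call rate < 0.95, minor allele frequency < 0.05,
#' or the Hardy-Weinberg exact-test p-value falls below 1e-5, after
#' restriction to autosomes 1..29. All comparisons are strict, so boundary
#' values are retained.
#'
#' @param min_call_rate minimum SNP call rate (fraction).
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_cutoff Hardy-Weinberg p-value cutoff.
#' @param n_autosomes number of autosomes retained (labels 1..n).
#' @param hwe_per_population test HWE within each population and drop a SNP
#'   if it fails in any (default: pooled cohort).
#' @param hwe_method `"exact"` (mid-less exact test) or `"chisq"`.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.95, min_maf = 0.05,
                      hwe_p_cutoff = 1e-5, n_autosomes = 29,
                      hwe_per_population = FALSE,
                      hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            hwe_p_cutoff > 0, hwe_p_cutoff < 1, n_autosomes >= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_cutoff = hwe_p_cutoff, n_autosomes = n_autosomes,
                 hwe_per_population = hwe_per_population,
                 hwe_method = hwe_method),
            class = "qc_params")
}

#' SNP call rate
#'
#' @param dataset a `genotype_dataset`.
#' @param snp_index SNP column index.
#' @return Fraction of samples with a non-missing call, in `[0, 1]`.
#' @export
snp_call_rate <- function(dataset, snp_index) {
  g <- dataset$calls[, snp_index]
  sum(!is.na(g)) / length(g)
}

#' Minor allele frequency
#'
#' Computed from allele counts of the counted allele (`allele_b`) over
#' non-missing genotypes; `min(p, 1 - p)`.
#'
#' @param dataset a `genotype_dataset`.
#' @param snp_index SNP column index.
#' @return Frequency in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(dataset, snp_index) {
  g <- dataset$calls[, snp_index]
  g <- g[!is.na(g)]
  if (!length(g)) stop("MAF undefined: all genotypes missing at SNP ",
                       dataset$snps$snp_id[snp_index])
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (Wigginton-style recurrence). Monomorphic SNPs return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1.0)
  # heterozygote counts share the parity of the rare-allele count
  het_vals <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- numeric(length(het_vals))
  # unnormalised recurrence upward from the smallest het count:
  # P(h+2)/P(h) = 4 * n_rare_hom(h) * n_common_hom(h) / ((h+2)*(h+1))
  probs[1] <- 1
  if (length(het_vals) > 1) {
    for (k in seq_len(length(het_vals) - 1)) {
      h <- het_vals[k]
      rare_hom <- (n_rare - h) / 2
      common_hom <- n - h - rare_hom
      probs[k + 1] <- probs[k] * 4 * rare_hom * common_hom /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, het_vals)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele parity")
  # relative epsilon keeps mathematically tied counts together
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

hwe_chisq_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1.0)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

hwe_p_for_snp <- function(g, method) {
  n0 <- sum(g == 0L, na.rm = TRUE)
  n1 <- sum(g == 1L, na.rm = TRUE)
  n2 <- sum(g == 2L, na.rm = TRUE)
  if (n0 + n1 + n2 == 0) return(1.0)
  if (method == "exact") hwe_exact_p(n0, n1, n2) else hwe_chisq_p(n0, n1, n2)
}

#' Apply marker quality control
#'
#' Stages run in fixed order, each on the previous stage's output:
#' autosome subset (chromosome labels 1..`n_autosomes`), call rate, MAF,
#' Hardy-Weinberg. Removal is strict (`< threshold`); boundary markers stay.
#'
#' @param dataset a `genotype_dataset`.
#' @param params a [qc_params()] object.
#' @return List with elements `dataset` (filtered) and `report` (a
#'   `qc_report`: per-stage attrition plus removed SNP ids with reasons).
#' @export
apply_qc <- function(dataset, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  removed <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  stages <- list()
  log_stage <- function(name, before, after) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name, snps_before = before, snps_after = after,
      stringsAsFactors = FALSE)
  }
  drop_snps <- function(ds, bad, reason) {
    if (any(bad)) {
      removed <<- rbind(removed,
                        data.frame(snp_id = ds$snps$snp_id[bad],
                                   reason = reason, stringsAsFactors = FALSE))
      ds <- subset_dataset(ds, snps = which(!bad))
    }
    ds
  }

  ds <- dataset
  n0 <- nrow(ds$snps)
  auto <- as.character(seq_len(params$n_autosomes))
  bad <- !(as.character(ds$snps$chrom) %in% auto)
  ds <- drop_snps(ds, bad, "non_autosomal")
  log_stage("autosome", n0, nrow(ds$snps))
  if (nrow(ds$snps) == 0) stop("no SNPs left after autosome subset")

  n1 <- nrow(ds$snps)
  cr <- colMeans(!is.na(ds$calls))
  ds <- drop_snps(ds, cr < params$min_call_rate, "call_rate")
  log_stage("call_rate", n1, nrow(ds$snps))
  if (nrow(ds$snps) == 0) stop("no SNPs left after call-rate filter")

  n2 <- nrow(ds$snps)
  p <- colMeans(ds$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  ds <- drop_snps(ds, maf < params$min_maf, "maf")
  log_stage("maf", n2, nrow(ds$snps))
  if (nrow(ds$snps) == 0) stop("no SNPs left after MAF filter")

  n3 <- nrow(ds$snps)
  if (params$hwe_per_population) {
    pops <- unique(ds$samples$population)
    pmat <- vapply(pops, function(pp) {
      rows <- ds$samples$population == pp
      apply(ds$calls[rows, , drop = FALSE], 2, hwe_p_for_snp,
            method = params$hwe_method)
    }, numeric(nrow(ds$snps)))
    hwe_p <- apply(as.matrix(pmat), 1, min)
  } else {
    hwe_p <- apply(ds$calls, 2, hwe_p_for_snp, method = params$hwe_method)
  }
  ds <- drop_snps(ds, hwe_p < params$hwe_p_cutoff, "hwe")
  log_stage("hwe", n3, nrow(ds$snps))
  if (nrow(ds$snps) == 0) stop("no SNPs left after HWE filter")

  report <- structure(list(stages = do.call(rbind, stages),
                           removed = removed,
                           n_samples = nrow(ds$samples)),
                      class = "qc_report")
  list(dataset = ds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$n_samples, " samples):\n", sep = "")
  print(x$stages, row.names = FALSE)
  cat(nrow(x$removed), "SNPs removed in total\n")
  invisible(x)
}
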