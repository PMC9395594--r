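#' Homozygosity-excess inbreeding coefficient F_HOM
#'
#' Method-of-moments estimator from the excess of observed over expected
#' homozygous genotypes: `F_HOM = (O_HOM - E_HOM) / (L - E_HOM)`, where `L`
#' is the sample's number of non-missing autosomal genotypes, `O_HOM` its
#' observed homozygote count, and `E_HOM = sum_j (1 - 2 p_j q_j * n_j /
#' (n_j - 1))` over the sample's non-missing SNPs, with `p_j` the cohort
#' allele frequency and `n_j` the non-missing allele count at SNP j (the
#' small-sample correction of the standard `--het`-style estimator).
#' Negative values indicate heterozygosity excess.
#'
#' @param dataset a `genotype_dataset` (after QC).
#' @return data.frame: `sample_id`, `population`, `o_hom`, `e_hom`, `l`,
#'   `f_hom` (`NA` where `L = E_HOM`).
#' @export
compute_fhom <- function(dataset) {
  g <- dataset$calls
  n_allele <- 2 * colSums(!is.na(g))            # n_j per SNP
  p <- colSums(g, na.rm = TRUE) / n_allele
  corr <- ifelse(n_allele > 1, n_allele / (n_allele - 1), NA_real_)
  exp_hom_snp <- 1 - 2 * p * (1 - p) * corr      # per-SNP expected hom prob
  obs <- !is.na(g)
  o_hom <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  l <- rowSums(obs)
  e_hom <- as.numeric(obs %*% ifelse(is.na(exp_hom_snp), 0, exp_hom_snp))
  denom <- l - e_hom
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (o_hom - e_hom) / denom)
  data.frame(sample_id = dataset$samples$sample_id,
             population = dataset$samples$population,
             o_hom = o_hom, e_hom = e_hom, l = l, f_hom = f,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' `F_ROH = L_ROH / L_AUTO`: the summed length of an individual's ROH
#' divided by the autosomal length covered by SNPs. Samples without
#' segments get 0.
#'
#' @param roh_set a `roh_set`.
#' @param l_auto autosome length denominator in bp (use [l_auto_bp()] for
#'   the data-derived default, or a fixed replication value).
#' @param dataset optional `genotype_dataset` supplying the sample table.
#' @return data.frame: `sample_id`, `population`, `l_roh_bp`, `f_roh`.
#' @export
compute_froh <- function(roh_set, l_auto, dataset = NULL) {
  stopifnot(l_auto > 0)
  samples <- roh_set_samples(roh_set, dataset)
  l_roh <- tapply(roh_set$length_bp,
                  factor(roh_set$sample_id, levels = samples$sample_id), sum)
  l_roh[is.na(l_roh)] <- 0
  data.frame(sample_id = samples$sample_id,
             population = samples$population,
             l_roh_bp = as.numeric(l_roh),
             f_roh = as.numeric(l_roh) / l_auto,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' F_ROH by ROH length class
#'
#' Per-sample F_ROH restricted to segments of each length class; the class
#' values partition total F_ROH exactly. Also returns the per-population
#' mean and standard deviation per class.
#'
#' @inheritParams compute_froh
#' @param scheme a [length_class_scheme()].
#' @return List with `per_sample` (sample x class F_ROH plus `total`) and
#'   `population_summary` (population, class, mean, sd to 2 decimals).
#' @export
froh_by_class <- function(roh_set, l_auto, scheme = length_class_scheme(),
                          dataset = NULL) {
  stopifnot(l_auto > 0)
  samples <- roh_set_samples(roh_set, dataset)
  cls <- if (nrow(roh_set))
    scheme$labels[findInterval(roh_set$length_bp / 1e6, scheme$boundaries_mb)]
  else character(0)
  mat <- matrix(0, nrow(samples), length(scheme$labels),
                dimnames = list(samples$sample_id, scheme$labels))
  if (nrow(roh_set)) {
    agg <- tapply(roh_set$length_bp,
                  list(factor(roh_set$sample_id, levels = samples$sample_id),
                       factor(cls, levels = scheme$labels)), sum)
    agg[is.na(agg)] <- 0
    mat[] <- agg / l_auto
  }
  per_sample <- data.frame(sample_id = samples$sample_id,
                           population = samples$population,
                           mat, total = rowSums(mat),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = NULL)
  pops <- sort(unique(samples$population))
  summ <- do.call(rbind, lapply(pops, function(pp) {
    rows <- per_sample$population == pp
    do.call(rbind, lapply(scheme$labels, function(cl) {
      v <- per_sample[rows, cl]
      data.frame(population = pp, class = cl,
                 mean = round(mean(v), 2),
                 sd = round(stats::sd(v), 2), stringsAsFactors = FALSE)
    }))
  }))
  list(per_sample = per_sample, population_summary = summ)
}

#' F_ROH by chromosome
#'
#' Per chromosome the denominator is that chromosome's SNP-covered span.
#' Chromosomes with fewer than 2 SNPs are excluded with a warning.
#'
#' @param roh_set a `roh_set`.
#' @param dataset the `genotype_dataset` (supplies spans and samples).
#' @return data.frame: `sample_id`, `population`, one column per chromosome.
#' @export
froh_by_chromosome <- function(roh_set, dataset) {
  spans <- chrom_spans(dataset$snps)
  drop <- spans$n_snps < 2
  if (any(drop)) {
    warning("excluding chromosome(s) with < 2 SNPs: ",
            paste(spans$chrom[drop], collapse = ", "))
    spans <- spans[!drop, , drop = FALSE]
  }
  samples <- dataset$samples
  mat <- matrix(0, nrow(samples), nrow(spans),
                dimnames = list(samples$sample_id, spans$chrom))
  if (nrow(roh_set)) {
    agg <- tapply(roh_set$length_bp,
                  list(factor(roh_set$sample_id, levels = samples$sample_id),
                       factor(as.character(roh_set$chrom),
                              levels = spans$chrom)), sum)
    agg[is.na(agg)] <- 0
    mat[] <- sweep(agg, 2, spans$last_bp - spans$first_bp, "/")
  }
  data.frame(sample_id = samples$sample_id, population = samples$population,
             mat, check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Correlation between F_ROH and F_HOM
#'
#' Pearson correlation of the two per-sample inbreeding coefficients within
#' each group (population by default). Groups of fewer than 3 samples or
#' with zero variance in either coefficient return `NA`.
#'
#' @param inbreeding_table data.frame with `f_roh`, `f_hom` and a grouping
#'   column.
#' @param grouping name of the grouping column (default `"population"`).
#' @return data.frame: group, `n`, `correlation`.
#' @export
froh_fhom_correlation <- function(inbreeding_table,
                                  grouping = "population") {
  stopifnot(all(c("f_roh", "f_hom", grouping) %in% names(inbreeding_table)))
  groups <- sort(unique(inbreeding_table[[grouping]]))
  do.call(rbind, lapply(groups, function(gg) {
    rows <- inbreeding_table[[grouping]] == gg
    x <- inbreeding_table$f_roh[rows]
    y <- inbreeding_table$f_hom[rows]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      NA_real_
    else stats::cor(x[ok], y[ok])
    stats::setNames(
      data.frame(gg, sum(ok), r, stringsAsFactors = FALSE),
      c(grouping, "n", "correlation"))
  }))
}

#' Per-sample inbreeding table
#'
#' Convenience wrapper combining [compute_fhom()] and [compute_froh()].
#'
#' @param dataset a `genotype_dataset`.
#' @param roh_set a `roh_set` for the same cohort.
#' @param l_auto denominator in bp; `NULL` uses [l_auto_bp()] on the dataset.
#' @return data.frame with F_HOM intermediates and F_ROH per sample.
#' @export
inbreeding_table <- function(dataset, roh_set, l_auto = NULL) {
  if (is.null(l_auto)) l_auto <- l_auto_bp(dataset)
  fh <- compute_fhom(dataset)
  fr <- compute_froh(roh_set, l_auto, dataset = dataset)
  cbind(fh, fr[match(fh$sample_id, fr$sample_id),
               c("l_roh_bp", "f_roh"), drop = FALSE])
}
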