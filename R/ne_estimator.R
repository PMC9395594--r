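#' Ne-estimation parameters
#'
#' Defaults pair SNPs 50 kb to 4 Mb apart in 30 equal-width bins which, at
#' 1 cM/Mb, probes roughly 12 to 1000 generations ago via `t = 1/(2c)`.
#'
#' @param min_dist_bp,max_dist_bp physical distance window for SNP pairs.
#' @param n_bins number of equal-width distance bins.
#' @param alpha mutation adjustment in the expected-r2 model (1 = none;
#'   2.2 is the usual mutation-adjusted choice).
#' @param sample_size_correction subtract `1/n` from each bin's mean r2.
#' @param map_rate cM per Mb used to convert bp to Morgans when the map has
#'   no genetic positions.
#' @param min_maf minor-allele-frequency floor applied before pairing.
#' @return A list of class `ne_params`.
#' @export
ne_params <- function(min_dist_bp = 5e4, max_dist_bp = 4e6, n_bins = 30,
                      alpha = 1, sample_size_correction = TRUE,
                      map_rate = 1.0, min_maf = 0.05) {
  stopifnot(min_dist_bp < max_dist_bp, n_bins >= 1, alpha > 0,
            map_rate > 0, min_maf >= 0, min_maf < 0.5)
  structure(list(min_dist_bp = min_dist_bp, max_dist_bp = max_dist_bp,
                 n_bins = n_bins, alpha = alpha,
                 sample_size_correction = sample_size_correction,
                 map_rate = map_rate, min_maf = min_maf),
            class = "ne_params")
}

#' Genotypic r-squared between two SNPs
#'
#' Squared Pearson correlation of genotype dosages across samples
#' non-missing at both SNPs (composite, phase-free LD).
#'
#' @param dataset a `genotype_dataset`.
#' @param snp_i,snp_j SNP column indices on the same chromosome.
#' @return r2 in `[0, 1]`, or `NA` if fewer than 2 shared complete samples
#'   or zero variance at either SNP.
#' @export
genotype_r2 <- function(dataset, snp_i, snp_j) {
  if (as.character(dataset$snps$chrom[snp_i]) !=
      as.character(dataset$snps$chrom[snp_j]))
    stop("SNPs are on different chromosomes")
  x <- dataset$calls[, snp_i]
  y <- dataset$calls[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

# pairwise r2 for all same-chromosome pairs within the distance window,
# using the pairwise-complete correlation matrix per chromosome
ld_pairs <- function(dataset, params) {
  out <- list()
  freq <- colMeans(dataset$calls, na.rm = TRUE) / 2
  maf_ok <- pmin(freq, 1 - freq) >= params$min_maf & !is.na(freq)
  for (idx in chrom_blocks(dataset$snps)) {
    idx <- idx[maf_ok[idx]]
    if (length(idx) < 2) next
    bp <- dataset$snps$bp_pos[idx]
    suppressWarnings(
      cc <- stats::cor(dataset$calls[, idx, drop = FALSE],
                       use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- bp[pr[, 2]] - bp[pr[, 1]]
    keep <- d >= params$min_dist_bp & d < params$max_dist_bp &
      !is.na(cc[pr])
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(dist_bp = d[keep],
                                         r2 = cc[pr][keep]^2)
  }
  if (!length(out)) return(data.frame(dist_bp = numeric(0), r2 = numeric(0)))
  do.call(rbind, out)
}

#' Mean adjusted r-squared per distance bin
#'
#' All intra-chromosomal SNP pairs with bp distance in
#' `[min_dist_bp, max_dist_bp)` are assigned to `n_bins` equal-width bins.
#' Per bin the mean r2 is reduced by `1/n` (n = samples) when the
#' sample-size correction is on, floored at a small positive epsilon. The
#' bin's genetic distance is `map_rate * mean bp distance / 1e8` Morgans.
#' Empty bins are dropped with a warning.
#'
#' @param dataset a QC'd `genotype_dataset`.
#' @param params an [ne_params()] object.
#' @return data.frame: `bin`, `c_morgans`, `mean_r2`, `mean_r2_adj`,
#'   `n_pairs`.
#' @export
bin_ld <- function(dataset, params = ne_params()) {
  pairs <- ld_pairs(dataset, params)
  breaks <- seq(params$min_dist_bp, params$max_dist_bp,
                length.out = params$n_bins + 1)
  bin <- findInterval(pairs$dist_bp, breaks, rightmost.closed = FALSE)
  bin[bin > params$n_bins] <- params$n_bins
  n <- nrow(dataset$samples)
  rows <- lapply(seq_len(params$n_bins), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    m_r2 <- mean(pairs$r2[sel])
    adj <- if (params$sample_size_correction) max(m_r2 - 1 / n, 1e-6) else m_r2
    data.frame(bin = b,
               c_morgans = params$map_rate * mean(pairs$dist_bp[sel]) / 1e8,
               mean_r2 = m_r2, mean_r2_adj = adj, n_pairs = sum(sel))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) warning(dropped, " empty distance bin(s) dropped")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin = integer(0), c_morgans = numeric(0),
                      mean_r2 = numeric(0), mean_r2_adj = numeric(0),
                      n_pairs = integer(0))
  out
}

#' Ne and time point from one LD bin
#'
#' From the drift expectation `E[r2] = 1/(alpha + 4 Ne c)`:
#' `Ne = (1/r2 - alpha) / (4c)`, probing `t = 1/(2c)` generations ago.
#'
#' @param mean_r2_adj sample-size-adjusted mean r2 in `(0, 1)`.
#' @param c genetic distance in Morgans (> 0).
#' @param alpha mutation adjustment (default 1).
#' @return List with `t` (generations, nearest integer) and `ne` (nearest
#'   integer).
#' @export
ne_from_bin <- function(mean_r2_adj, c, alpha = 1) {
  if (is.na(mean_r2_adj) || mean_r2_adj <= 0 || mean_r2_adj >= 1)
    stop("mean_r2_adj must lie strictly between 0 and 1")
  stopifnot(c > 0)
  list(t = round(1 / (2 * c)),
       ne = round((1 / mean_r2_adj - alpha) / (4 * c)))
}

#' LD-decay Ne trajectory
#'
#' Composes [bin_ld()] and [ne_from_bin()] per population; bins with
#' adjusted r2 outside `(0, 1)` are dropped. Output is sorted by `t`
#' ascending (recent first).
#'
#' @param dataset a QC'd `genotype_dataset`.
#' @param params an [ne_params()] object.
#' @param by_population estimate per population (default) or on the pooled
#'   cohort.
#' @return data.frame: `population`, `t`, `c_morgans`, `mean_r2_adj`, `ne`,
#'   `n_pairs`.
#' @export
ne_trajectory <- function(dataset, params = ne_params(),
                          by_population = TRUE) {
  groups <- if (by_population)
    split(seq_len(nrow(dataset$samples)), dataset$samples$population)
  else list(ALL = seq_len(nrow(dataset$samples)))
  out <- lapply(names(groups), function(gn) {
    ds <- subset_dataset(dataset, samples = groups[[gn]])
    bins <- bin_ld(ds, params)
    bins <- bins[bins$mean_r2_adj > 0 & bins$mean_r2_adj < 1, , drop = FALSE]
    if (nrow(bins) < 1)
      stop("population ", gn, ": no usable LD bins for Ne estimation")
    est <- lapply(seq_len(nrow(bins)), function(i)
      ne_from_bin(bins$mean_r2_adj[i], bins$c_morgans[i], params$alpha))
    res <- data.frame(population = gn,
                      t = vapply(est, `[[`, numeric(1), "t"),
                      c_morgans = bins$c_morgans,
                      mean_r2_adj = bins$mean_r2_adj,
                      ne = vapply(est, `[[`, numeric(1), "ne"),
                      n_pairs = bins$n_pairs, stringsAsFactors = FALSE)
    res[order(res$t), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
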