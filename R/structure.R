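#' LD-pruning parameters
#'
#' Defaults mirror the common `--indep-pairwise 50 5 0.5` protocol: windows
#' of 50 SNPs advanced by 5, removing one SNP of every pair with genotypic
#' r2 above 0.5.
#'
#' @param window_snps window size in SNPs.
#' @param step_snps window step in SNPs.
#' @param r2_max maximum tolerated pairwise r2.
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_snps = 50, step_snps = 5, r2_max = 0.5) {
  stopifnot(window_snps > step_snps, step_snps >= 1,
            r2_max > 0, r2_max <= 1)
  structure(list(window_snps = window_snps, step_snps = step_snps,
                 r2_max = r2_max), class = "prune_params")
}

#' Greedy windowed LD pruning
#'
#' Within each window, while any retained pair has genotypic r2 above
#' `r2_max`, the member with the lower MAF is removed (tie: the later map
#' position); the window then advances by `step_snps`. Fully deterministic.
#'
#' @param dataset a QC'd `genotype_dataset`.
#' @param params a [prune_params()] object.
#' @return Sorted integer vector of retained SNP column indices.
#' @export
ld_prune <- function(dataset, params = prune_params()) {
  freq <- colMeans(dataset$calls, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- rep(TRUE, nrow(dataset$snps))
  for (idx in chrom_blocks(dataset$snps)) {
    m <- length(idx)
    starts <- seq(1L, max(1L, m), by = params$step_snps)
    for (st in starts) {
      win <- idx[st:min(st + params$window_snps - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      suppressWarnings(
        cc <- stats::cor(dataset$calls[, win, drop = FALSE],
                         use = "pairwise.complete.obs")^2)
      repeat {
        cc[is.na(cc)] <- 0
        diag(cc) <- 0
        mx <- which(cc > params$r2_max, arr.ind = TRUE)
        if (!nrow(mx)) break
        i <- mx[1, 1]; j <- mx[1, 2]
        # drop the lower-MAF member; tie -> later map position
        drop_local <- if (maf[win[i]] < maf[win[j]]) i
                      else if (maf[win[j]] < maf[win[i]]) j
                      else max(i, j)
        keep[win[drop_local]] <- FALSE
        cc[drop_local, ] <- 0
        cc[, drop_local] <- 0
      }
    }
  }
  which(keep)
}

#' Identity-by-state similarity matrix
#'
#' `IBS(i, j)` is the mean over SNPs non-missing in both samples of
#' `(2 - |dosage_i - dosage_j|) / 2`; symmetric with unit diagonal. Pairs
#' sharing no non-missing SNP get `NA`.
#'
#' @param dataset a `genotype_dataset` with at least 2 samples.
#' @return Numeric matrix with sample ids as dimnames.
#' @export
ibs_matrix <- function(dataset) {
  g <- dataset$calls
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples")
  obs <- !is.na(g)
  shared <- obs %*% t(obs)
  # per dosage level indicators restricted to observed calls
  lev <- lapply(0:2, function(v) (obs & g == v) * 1)
  absdiff <- matrix(0, n, n)
  for (a in 0:2) for (b in 0:2) {
    if (a == b) next
    absdiff <- absdiff + abs(a - b) * (lev[[a + 1]] %*% t(lev[[b + 1]]))
  }
  ibs <- (2 * shared - absdiff) / (2 * shared)
  ibs[shared == 0] <- NA_real_
  diag(ibs) <- 1
  dimnames(ibs) <- list(dataset$samples$sample_id, dataset$samples$sample_id)
  ibs
}

#' Remove related individuals by IBS
#'
#' While any pair exceeds the cutoff, the member with the lower call rate is
#' removed (tie: the lexicographically larger sample id). Deterministic.
#'
#' @param dataset a `genotype_dataset`.
#' @param ibs_cutoff similarity cutoff in `(0, 1)` (strict `>` removal).
#' @return The reduced `genotype_dataset`.
#' @export
remove_related <- function(dataset, ibs_cutoff = 0.65) {
  stopifnot(ibs_cutoff > 0, ibs_cutoff < 1)
  ibs <- ibs_matrix(dataset)
  call_rate <- rowMeans(!is.na(dataset$calls))
  ids <- dataset$samples$sample_id
  active <- rep(TRUE, length(ids))
  repeat {
    m <- ibs
    m[!active, ] <- NA; m[, !active] <- NA
    diag(m) <- NA
    if (all(is.na(m)) || max(m, na.rm = TRUE) <= ibs_cutoff) break
    w <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- w[1]; j <- w[2]
    drop <- if (call_rate[i] < call_rate[j]) i
            else if (call_rate[j] < call_rate[i]) j
            else if (ids[i] > ids[j]) i else j
    active[drop] <- FALSE
  }
  subset_dataset(dataset, samples = which(active))
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per SNP; dosages are centred by `2p` and
#' scaled by `sqrt(2p(1-p))` (Patterson scaling); SNPs fixed in the cohort
#' are dropped. Coordinates are the projections onto the top `k` right
#' singular directions of the scaled matrix (equivalently the top-k
#' eigendecomposition of the sample covariance).
#'
#' @param dataset a pruned `genotype_dataset`.
#' @param k number of components (`<= n_samples - 1`).
#' @return List of class `pca_result`: `coordinates` (data.frame with
#'   sample_id, population, PC1..PCk), `eigenvalues`, `variance_fraction`.
#' @export
pca_genotypes <- function(dataset, k = 10) {
  n <- nrow(dataset$samples)
  if (k > n - 1) stop("k must be at most n_samples - 1")
  g <- dataset$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  usable <- !is.na(p) & p > 0 & p < 1
  g <- g[, usable, drop = FALSE]
  p <- p[usable]
  for (j in seq_len(ncol(g))) {
    mj <- is.na(g[, j])
    if (any(mj)) g[mj, j] <- 2 * p[j]
  }
  z <- sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(z, nu = k, nv = 0)
  eig <- sv$d^2 / (n - 1)               # eigenvalues of the sample covariance
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(
    coordinates = data.frame(sample_id = dataset$samples$sample_id,
                             population = dataset$samples$population,
                             coords, stringsAsFactors = FALSE,
                             row.names = NULL),
    eigenvalues = eig[seq_len(k)],
    variance_fraction = eig[seq_len(k)] / sum(eig)),
    class = "pca_result")
}
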