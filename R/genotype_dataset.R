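#' Construct a genotype dataset
#'
#' The central container of the package: a samples x SNPs matrix of diploid
#' genotype dosages together with the marker map and per-sample population
#' labels. Dosage counts copies of `allele_b`, so `0` = homozygous for
#' `allele_a`, `1` = heterozygous, `2` = homozygous for `allele_b` and `NA` =
#' missing. Counting a fixed allele (rather than trusting file column order)
#' keeps minor-allele frequencies unambiguous across PLINK dialects.
#'
#' @param snps data.frame with columns `chrom` (chromosome label; autosomes
#'   are integer-coded), `snp_id`, `genetic_pos` (centiMorgans, may be 0),
#'   `bp_pos` (1-based base pairs), `allele_a`, `allele_b`. Must be sorted by
#'   chromosome block and, within a chromosome, by ascending `bp_pos`.
#' @param samples data.frame with columns `sample_id` (unique) and
#'   `population` (non-empty label).
#' @param calls integer matrix, `nrow(samples)` x `nrow(snps)`, values in
#'   \{0, 1, 2, NA\}.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(snps, samples, calls) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  needed <- c("chrom", "snp_id", "genetic_pos", "bp_pos", "allele_a", "allele_b")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols))
    stop("snps is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id and population")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id: ", snps$snp_id[duplicated(snps$snp_id)][1])
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ", samples$sample_id[duplicated(samples$sample_id)][1])
  if (any(!nzchar(samples$population)))
    stop("population labels must be non-empty")
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps))
    stop(sprintf("calls is %d x %d but expected %d samples x %d SNPs",
                 nrow(calls), ncol(calls), nrow(samples), nrow(snps)))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(snps$bp_pos <= 0)) stop("bp_pos must be positive")
  # chromosome blocks contiguous, positions ascending within each block
  r <- rle(as.character(snps$chrom))
  if (anyDuplicated(r$values))
    stop("chromosome blocks must be contiguous in SNP order")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(starts)) {
    bp <- snps$bp_pos[starts[k]:ends[k]]
    if (is.unsorted(bp))
      stop("SNPs on chromosome ", r$values[k], " are not sorted by bp_pos")
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$snp_id
  rownames(snps) <- NULL
  rownames(samples) <- NULL
  structure(list(snps = snps, samples = samples, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf("genotype_dataset: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$samples), nrow(x$snps),
              length(unique(x$snps$chrom))))
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param x a `genotype_dataset`.
#' @param samples sample index (integer/logical) or sample_id vector; `NULL`
#'   keeps all.
#' @param snps SNP index (integer/logical) or snp_id vector; `NULL` keeps all.
#'   Index order must preserve map sortedness.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$samples))
        else if (is.character(samples)) match(samples, x$samples$sample_id)
        else samples
  vi <- if (is.null(snps)) seq_len(nrow(x$snps))
        else if (is.character(snps)) match(snps, x$snps$snp_id)
        else snps
  genotype_dataset(x$snps[vi, , drop = FALSE],
                   x$samples[si, , drop = FALSE],
                   x$calls[si, vi, drop = FALSE])
}

# indices of each chromosome block, in map order
chrom_blocks <- function(snps) {
  split(seq_len(nrow(snps)), factor(as.character(snps$chrom),
                                    levels = unique(as.character(snps$chrom))))
}

# span (first..last mapped bp) per chromosome
chrom_spans <- function(snps) {
  blocks <- chrom_blocks(snps)
  data.frame(
    chrom = names(blocks),
    first_bp = vapply(blocks, function(i) min(snps$bp_pos[i]), numeric(1)),
    last_bp = vapply(blocks, function(i) max(snps$bp_pos[i]), numeric(1)),
    n_snps = lengths(blocks),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Autosomal length covered by SNPs
#'
#' Sum over chromosomes of (last - first) mapped SNP position, in base pairs.
#' Used as the default denominator of F_ROH.
#'
#' @param dataset a `genotype_dataset`.
#' @return Length in bp.
#' @export
l_auto_bp <- function(dataset) {
  sp <- chrom_spans(dataset$snps)
  sum(sp$last_bp - sp$first_bp)
}
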