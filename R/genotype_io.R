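#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a PED/MAP pair into a [genotype_dataset()]. The MAP file supplies
#' the marker map (chrom, snp_id, cM, bp); the PED file supplies six metadata
#' columns (family, individual, father, mother, sex, phenotype) followed by
#' two allele columns per SNP. The population label is taken from the PED
#' family-ID column. A genotype is missing iff either allele is "0".
#'
#' Allele roles are assigned deterministically: at each SNP the
#' lexicographically smaller observed allele becomes `allele_a` and the larger
#' `allele_b` (the counted allele). A monomorphic SNP gets `allele_b = "0"`.
#' SNPs are reordered by (chromosome block, bp) with autosome-coded
#' chromosomes first in numeric order.
#'
#' @param ped_source path to the PED file.
#' @param map_source path to the MAP file.
#' @return A `genotype_dataset`.
#' @export
read_ped_map <- function(ped_source, map_source) {
  map <- utils::read.table(map_source, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"),
                           col.names = c("chrom", "snp_id", "genetic_pos",
                                         "bp_pos"))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in MAP: ",
         map$snp_id[duplicated(map$snp_id)][1])
  n_snps <- nrow(map)
  lines <- readLines(ped_source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file has no samples")
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * n_snps
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != expected)
      stop(sprintf(
        "PED row %d has %d fields but MAP implies %d (6 + 2 x %d SNPs)",
        i, length(fields[[i]]), expected, n_snps))
  }
  meta <- t(vapply(fields, function(f) f[1:6], character(6)))
  a1 <- t(vapply(fields, function(f) f[6L + 2L * seq_len(n_snps) - 1L],
                 character(n_snps)))
  a2 <- t(vapply(fields, function(f) f[6L + 2L * seq_len(n_snps)],
                 character(n_snps)))
  dim(a1) <- dim(a2) <- c(length(fields), n_snps)

  allele_a <- allele_b <- character(n_snps)
  calls <- matrix(NA_integer_, nrow(a1), n_snps)
  for (j in seq_len(n_snps)) {
    x <- a1[, j]; y <- a2[, j]
    ok <- x != "0" & y != "0"
    obs <- sort(unique(c(x[ok], y[ok])))
    if (length(obs) > 2L)
      stop("SNP ", map$snp_id[j], " has more than two alleles")
    allele_a[j] <- if (length(obs) >= 1L) obs[1] else "0"
    allele_b[j] <- if (length(obs) == 2L) obs[2] else "0"
    calls[ok, j] <- (x[ok] == allele_b[j]) + (y[ok] == allele_b[j])
  }
  snps <- data.frame(chrom = map$chrom, snp_id = map$snp_id,
                     genetic_pos = map$genetic_pos, bp_pos = map$bp_pos,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  ord <- map_order(snps)
  samples <- data.frame(sample_id = meta[, 2], population = meta[, 1],
                        stringsAsFactors = FALSE)
  genotype_dataset(snps[ord, , drop = FALSE], samples,
                   calls[, ord, drop = FALSE])
}

# deterministic map order: numeric chromosomes ascending, then others
# in order of first appearance; bp ascending within chromosome
map_order <- function(snps) {
  ch <- as.character(snps$chrom)
  num <- suppressWarnings(as.numeric(ch))
  first_seen <- match(ch, unique(ch))
  key <- ifelse(is.na(num), 1e6 + first_seen, num)
  order(key, snps$bp_pos)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_ped_map()]. Missing genotypes are written as "0 0";
#' heterozygotes are written in the fixed order (`allele_a`, `allele_b`)
#' since PED carries no phase.
#'
#' @param dataset a `genotype_dataset`.
#' @param ped_sink,map_sink output paths.
#' @return Invisibly, `NULL`.
#' @export
write_ped_map <- function(dataset, ped_sink, map_sink) {
  sn <- dataset$snps
  utils::write.table(
    data.frame(sn$chrom, sn$snp_id, sn$genetic_pos, sn$bp_pos),
    map_sink, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  g <- dataset$calls
  n <- nrow(g)
  rows <- character(n)
  # per-SNP allele pair strings indexed by dosage code
  geno_str <- rbind(paste(sn$allele_a, sn$allele_a),
                    paste(sn$allele_a, sn$allele_b),
                    paste(sn$allele_b, sn$allele_b))
  for (i in seq_len(n)) {
    gs <- geno_str[cbind(g[i, ] + 1L, seq_len(ncol(g)))]
    gs[is.na(g[i, ])] <- "0 0"
    rows[i] <- paste(dataset$samples$population[i],
                     dataset$samples$sample_id[i],
                     "0 0 0 -9", paste(gs, collapse = " "))
  }
  writeLines(rows, ped_sink)
  invisible(NULL)
}

# dosage lookup for one packed PLINK byte: 2-bit codes, sample-minor within
# byte; 0b00 = hom A1 (dosage 2 of the counted allele), 0b01 = missing,
# 0b10 = het, 0b11 = hom A2 (dosage 0)
plink_byte_lut <- function() {
  code_map <- c(2L, NA_integer_, 1L, 0L)
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255)
    for (k in 0:3)
      lut[b + 1L, k + 1L] <- code_map[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L]
  lut
}

#' Read PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' SNP-major BED decoding per the PLINK 1 format: magic bytes
#' `0x6c 0x1b 0x01`, then ceiling(n_samples/4) bytes per SNP, two bits per
#' sample (00 = homozygous for BIM allele 1, 01 = missing, 10 = heterozygous,
#' 11 = homozygous for BIM allele 2); padding bits of the last byte are
#' ignored. The BIM allele-1 column is the counted allele (`allele_b`),
#' allele 2 is `allele_a`. Population labels come from the FAM family-ID
#' column.
#'
#' @param bed_source,bim_source,fam_source file paths.
#' @return A `genotype_dataset`.
#' @export
read_bed_bim_fam <- function(bed_source, bim_source, fam_source) {
  bim <- utils::read.table(bim_source, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"),
                           col.names = c("chrom", "snp_id", "genetic_pos",
                                         "bp_pos", "a1", "a2"))
  fam <- tryCatch(utils::read.table(fam_source, header = FALSE,
                                    colClasses = "character"),
                  error = function(e) stop("FAM file has no samples"))
  if (nrow(fam) == 0) stop("FAM file has no samples")
  if (ncol(fam) < 6) stop("FAM must have 6 columns")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_source, "raw", n = file.size(bed_source))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
      raw[3] != as.raw(0x01))
    stop("not a SNP-major PLINK 1 BED file (bad magic bytes)")
  nb <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != nb * m)
    stop(sprintf("BED body has %d bytes but %d SNPs x %d samples need %d",
                 length(body), m, n, nb * m))
  lut <- plink_byte_lut()
  bytes <- matrix(as.integer(body), nrow = nb, ncol = m)
  calls <- matrix(NA_integer_, n, m)
  for (k in 1:4) {
    idx <- seq.int(k, by = 4L, length.out = nb)
    idx <- idx[idx <= n]
    if (length(idx))
      calls[idx, ] <- lut[bytes[seq_along(idx), , drop = FALSE] + 1L, k]
  }
  snps <- data.frame(chrom = bim$chrom, snp_id = bim$snp_id,
                     genetic_pos = bim$genetic_pos, bp_pos = bim$bp_pos,
                     allele_a = bim$a2, allele_b = bim$a1,
                     stringsAsFactors = FALSE)
  ord <- map_order(snps)
  samples <- data.frame(sample_id = fam[, 2], population = fam[, 1],
                        stringsAsFactors = FALSE)
  genotype_dataset(snps[ord, , drop = FALSE], samples,
                   calls[, ord, drop = FALSE])
}

#' Write PLINK 1 binary genotypes (BED/BIM/FAM)
#'
#' Inverse of [read_bed_bim_fam()]; emits SNP-major BED with `allele_b` in
#' the BIM allele-1 column.
#'
#' @param dataset a `genotype_dataset`.
#' @param bed_sink,bim_sink,fam_sink output paths.
#' @return Invisibly, `NULL`.
#' @export
write_bed_bim_fam <- function(dataset, bed_sink, bim_sink, fam_sink) {
  sn <- dataset$snps
  utils::write.table(
    data.frame(sn$chrom, sn$snp_id, sn$genetic_pos, sn$bp_pos,
               sn$allele_b, sn$allele_a),
    bim_sink, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(dataset$samples$population, dataset$samples$sample_id,
               0, 0, 0, -9),
    fam_sink, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  g <- dataset$calls
  n <- nrow(g)
  m <- ncol(g)
  nb <- ceiling(n / 4)
  # dosage -> 2-bit code (0:2 hom_a/het/hom_b -> 3,2,0; NA -> 1)
  code <- matrix(1L, nb * 4L, m)
  enc <- c(3L, 2L, 0L)
  for (j in seq_len(m)) {
    cj <- enc[g[, j] + 1L]
    cj[is.na(cj)] <- 1L
    code[seq_len(n), j] <- cj
    if (nb * 4L > n) code[(n + 1L):(nb * 4L), j] <- 0L
  }
  dim(code) <- c(4L, nb * m)
  bytes <- code[1, ] + bitwShiftL(code[2, ], 2L) +
    bitwShiftL(code[3, ], 4L) + bitwShiftL(code[4, ], 6L)
  con <- file(bed_sink, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(NULL)
}
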