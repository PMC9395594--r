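#' Per-SNP ROH incidence within a population
#'
#' For each SNP, the fraction of the population's individuals with at least
#' one ROH segment whose `start_bp`..`end_bp` interval contains the SNP
#' position (bp containment, robust to map edits).
#'
#' @param roh_set a `roh_set`.
#' @param dataset the `genotype_dataset`.
#' @param population population label (must exist in the dataset).
#' @return data.frame of class `incidence_track`: `chrom`, `bp_pos`,
#'   `snp_id`, `incidence` (fraction), `incidence_pct`.
#' @export
snp_incidence <- function(roh_set, dataset, population) {
  ids <- dataset$samples$sample_id[dataset$samples$population == population]
  if (!length(ids)) stop("unknown population '", population, "'")
  segs <- roh_set[roh_set$sample_id %in% ids, , drop = FALSE]
  counts <- integer(nrow(dataset$snps))
  for (idx in chrom_blocks(dataset$snps)) {
    ch <- as.character(dataset$snps$chrom[idx[1]])
    s <- segs[as.character(segs$chrom) == ch, , drop = FALSE]
    if (!nrow(s)) next
    bp <- dataset$snps$bp_pos[idx]
    # per individual, count each SNP at most once even with multiple segments
    for (sid in unique(s$sample_id)) {
      si <- s[s$sample_id == sid, , drop = FALSE]
      covered <- rep(FALSE, length(bp))
      for (r in seq_len(nrow(si)))
        covered <- covered | (bp >= si$start_bp[r] & bp <= si$end_bp[r])
      counts[idx] <- counts[idx] + covered
    }
  }
  structure(data.frame(chrom = as.character(dataset$snps$chrom),
                       bp_pos = dataset$snps$bp_pos,
                       snp_id = dataset$snps$snp_id,
                       incidence = counts / length(ids),
                       incidence_pct = 100 * counts / length(ids),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("incidence_track", "data.frame"),
            population = population, n_individuals = length(ids))
}

#' Call ROH islands from an incidence track
#'
#' Maximal runs of consecutive same-chromosome SNPs with incidence strictly
#' above the threshold become islands; runs with fewer than
#' `min_island_snps` SNPs are dropped. Island bounds are the first and last
#' qualifying SNP positions.
#'
#' @param track an `incidence_track` from [snp_incidence()].
#' @param threshold_fraction incidence threshold in `(0, 1]` (strict `>`).
#' @param min_island_snps minimum SNPs per island.
#' @return data.frame: `population`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_mb` (2 decimals), `peak_incidence_pct`.
#' @export
call_islands <- function(track, threshold_fraction, min_island_snps = 10) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  pop <- attr(track, "population")
  if (is.null(pop)) pop <- NA_character_
  out <- list()
  for (idx in split(seq_len(nrow(track)),
                    factor(track$chrom, levels = unique(track$chrom)))) {
    above <- track$incidence[idx] > threshold_fraction
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      a <- idx[starts[s]]; b <- idx[ends[s]]
      nsnp <- ends[s] - starts[s] + 1L
      if (nsnp < min_island_snps) next
      out[[length(out) + 1]] <- data.frame(
        population = pop, chrom = track$chrom[a],
        start_bp = track$bp_pos[a], end_bp = track$bp_pos[b],
        n_snps = nsnp,
        length_mb = segment_length_mb(track$bp_pos[a], track$bp_pos[b]),
        peak_incidence_pct = max(track$incidence_pct[a:b]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(population = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_mb = numeric(0),
                      peak_incidence_pct = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write islands as BED
#'
#' Converts the 1-based inclusive internal coordinates to BED's 0-based
#' half-open convention.
#'
#' @param islands data.frame from [call_islands()].
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
islands_to_bed <- function(islands, path) {
  bed <- data.frame(chrom = islands$chrom,
                    start = format(islands$start_bp - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(islands$end_bp, scientific = FALSE,
                                 trim = TRUE),
                    name = sprintf("%s_island_%d", islands$population,
                                   seq_len(nrow(islands))))
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
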