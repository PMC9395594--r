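#' ROH-calling parameters
#'
#' Defaults follow the common sliding-window protocol for 50K livestock
#' panels: 50-SNP scanning window, at least 50 consecutive SNPs and 1 Mb per
#' run, at most 5 missing calls and no heterozygotes inside a run, runs split
#' at inter-SNP gaps above 1 Mb, and a SNP enters a run when more than 5% of
#' the windows overlapping it are homozygous.
#'
#' @param window_snps sliding-window size in SNPs.
#' @param min_snps_in_roh minimum SNPs per reported run.
#' @param min_length_bp minimum run length in bp.
#' @param max_missing_in_roh maximum missing calls per window and per run.
#' @param max_het_in_roh maximum heterozygous calls per window and per run.
#' @param max_gap_bp maximum bp gap between adjacent SNPs inside a run.
#' @param window_hit_fraction minimum fraction of overlapping homozygous
#'   windows for a SNP to be flagged (strictly greater than).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, min_snps_in_roh = 50,
                       min_length_bp = 1e6, max_missing_in_roh = 5,
                       max_het_in_roh = 0, max_gap_bp = 1e6,
                       window_hit_fraction = 0.05) {
  stopifnot(window_snps >= 1, min_snps_in_roh >= 1, min_length_bp > 0,
            max_missing_in_roh >= 0, max_het_in_roh >= 0, max_gap_bp > 0,
            window_hit_fraction >= 0, window_hit_fraction < 1)
  structure(list(window_snps = window_snps,
                 min_snps_in_roh = min_snps_in_roh,
                 min_length_bp = min_length_bp,
                 max_missing_in_roh = max_missing_in_roh,
                 max_het_in_roh = max_het_in_roh,
                 max_gap_bp = max_gap_bp,
                 window_hit_fraction = window_hit_fraction),
            class = "roh_params")
}

#' ROH length-class scheme
#'
#' Left-closed, right-open classes on segment length in Mb. The default
#' boundaries 1, 5, 10, 20, 40 give the five standard classes 1-5, 5-10,
#' 10-20, 20-40 and >40 Mb.
#'
#' @param boundaries_mb strictly increasing lower bounds in Mb.
#' @return Object of class `length_class_scheme` with a `labels` element.
#' @export
length_class_scheme <- function(boundaries_mb = c(1, 5, 10, 20, 40)) {
  stopifnot(length(boundaries_mb) >= 1, all(diff(boundaries_mb) > 0))
  nb <- length(boundaries_mb)
  labels <- c(paste0(boundaries_mb[-nb], "-", boundaries_mb[-1], "Mb"),
              paste0(">", boundaries_mb[nb], "Mb"))
  structure(list(boundaries_mb = boundaries_mb, labels = labels),
            class = "length_class_scheme")
}

#' Segment length in Mb for reporting
#'
#' `(end_bp - start_bp) / 1e6`, rounded half-up to 2 decimals. Internal
#' computations keep the unrounded value; this is the reporting convention.
#'
#' @param start_bp,end_bp segment bounds in bp.
#' @return Length in Mb, 2 decimals.
#' @export
segment_length_mb <- function(start_bp, end_bp) {
  stopifnot(all(end_bp > start_bp))
  x <- (end_bp - start_bp) / 1e6
  # small guard so exact halves survive binary floating point (1.005 * 100
  # is fractionally below 100.5)
  floor(x * 100 + 0.5 + 1e-9) / 100
}

empty_segments <- function() {
  data.frame(sample_id = character(0), population = character(0),
             chrom = character(0), start_bp = numeric(0), end_bp = numeric(0),
             n_snps = integer(0), length_bp = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity in one individual
#'
#' Two-phase sliding-window scan. Phase 1: every window of `window_snps`
#' consecutive same-chromosome SNPs is homozygous if it holds at most
#' `max_het_in_roh` heterozygous and `max_missing_in_roh` missing calls; a
#' SNP is flagged when the fraction of homozygous windows among those
#' overlapping it exceeds `window_hit_fraction`. Phase 2: maximal stretches
#' of flagged SNPs become candidate runs, are split where adjacent SNPs are
#' more than `max_gap_bp` apart, and are discarded if they violate the
#' per-run heterozygote/missing limits or the minimum SNP-count/length
#' thresholds. Chromosomes with fewer SNPs than the window yield no calls.
#'
#' @param genotype_row integer vector of dosages aligned to `snp_map`.
#' @param snp_map the `snps` data.frame of a `genotype_dataset`.
#' @param params a [roh_params()] object.
#' @return data.frame of segments (`chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`), one row per run.
#' @export
detect_roh_individual <- function(genotype_row, snp_map,
                                  params = roh_params()) {
  stopifnot(inherits(params, "roh_params"),
            length(genotype_row) == nrow(snp_map))
  out <- list()
  for (idx in chrom_blocks(snp_map)) {
    g <- genotype_row[idx]
    bp <- snp_map$bp_pos[idx]
    if (is.unsorted(bp)) stop("snp_map not sorted by bp within chromosome")
    n <- length(g)
    w <- params$window_snps
    if (n < w) next
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    ch <- c(0, cumsum(het))
    cm <- c(0, cumsum(mis))
    k <- n - w + 1L                      # windows start at 1..k
    wh <- ch[(w + 1):(w + k)] - ch[1:k]  # het per window
    wm <- cm[(w + 1):(w + k)] - cm[1:k]
    hom_win <- as.integer(wh <= params$max_het_in_roh &
                            wm <= params$max_missing_in_roh)
    # windows overlapping SNP i start in [max(1, i-w+1), min(i, k)]
    cw <- c(0, cumsum(hom_win))
    i <- seq_len(n)
    lo <- pmax(1L, i - w + 1L)
    hi <- pmin(i, k)
    n_hom <- cw[hi + 1L] - cw[lo]
    n_tot <- hi - lo + 1L
    flagged <- n_tot > 0L & (n_hom / pmax(n_tot, 1L)) > params$window_hit_fraction

    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      a <- starts[s]; b <- ends[s]
      # split at large gaps
      cuts <- if (b > a) which(diff(bp[a:b]) > params$max_gap_bp) else integer(0)
      seg_starts <- a + c(0L, cuts)
      seg_ends <- c(a + cuts - 1L, b)
      for (t in seq_along(seg_starts)) {
        aa <- seg_starts[t]; bb <- seg_ends[t]
        nh <- ch[bb + 1L] - ch[aa]
        nm <- cm[bb + 1L] - cm[aa]
        nsnp <- bb - aa + 1L
        len <- bp[bb] - bp[aa]
        if (nh <= params$max_het_in_roh && nm <= params$max_missing_in_roh &&
            nsnp >= params$min_snps_in_roh && len >= params$min_length_bp) {
          out[[length(out) + 1]] <- data.frame(
            chrom = as.character(snp_map$chrom[idx[1]]),
            start_bp = bp[aa], end_bp = bp[bb],
            n_snps = nsnp, length_bp = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    e <- empty_segments()
    return(e[, c("chrom", "start_bp", "end_bp", "n_snps", "length_bp")])
  }
  do.call(rbind, out)
}

#' Detect runs of homozygosity for a cohort
#'
#' @param dataset a `genotype_dataset`.
#' @param params a [roh_params()] object.
#' @return A `roh_set`: data.frame of segments with `sample_id` and
#'   `population` columns, plus attributes used by summaries.
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  segs <- lapply(seq_len(nrow(dataset$samples)), function(i) {
    s <- detect_roh_individual(dataset$calls[i, ], dataset$snps, params)
    if (nrow(s) == 0) return(NULL)
    cbind(data.frame(sample_id = dataset$samples$sample_id[i],
                     population = dataset$samples$population[i],
                     stringsAsFactors = FALSE), s)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs)) segs <- empty_segments()
  rownames(segs) <- NULL
  structure(segs, class = c("roh_set", "data.frame"),
            samples = dataset$samples, params = params)
}

roh_set_samples <- function(roh_set, dataset = NULL) {
  if (!is.null(dataset)) return(dataset$samples)
  s <- attr(roh_set, "samples")
  if (is.null(s)) stop("roh_set carries no sample table; pass the dataset")
  s
}

#' Count segments per length class and population
#'
#' Every segment falls in exactly one left-closed, right-open class of the
#' scheme. Returns a class x population count table with a `Total` row and
#' column.
#'
#' @param roh_set a `roh_set` (or segment data.frame with `population` and
#'   `length_bp`).
#' @param scheme a [length_class_scheme()].
#' @return data.frame: `class`, one column per population, `Total`.
#' @export
classify_lengths <- function(roh_set, scheme = length_class_scheme()) {
  b <- scheme$boundaries_mb
  pops <- sort(unique(as.character(roh_set$population)))
  tab <- matrix(0L, length(scheme$labels), length(pops),
                dimnames = list(scheme$labels, pops))
  if (nrow(roh_set)) {
    mb <- roh_set$length_bp / 1e6
    cls <- findInterval(mb, b)
    if (any(cls == 0))
      warning(sum(cls == 0), " segment(s) below the first class boundary")
    keep <- cls >= 1
    tab[] <- table(factor(scheme$labels[cls[keep]], levels = scheme$labels),
                   factor(roh_set$population[keep], levels = pops))
  }
  out <- data.frame(class = rownames(tab), tab, Total = rowSums(tab),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  tot <- c(class = "Total", as.list(colSums(out[, -1, drop = FALSE])))
  rbind(out, as.data.frame(tot, check.names = FALSE))
}

#' Per-population ROH summary
#'
#' Mean segment count per individual (zero-ROH individuals included in the
#' denominator), mean segment length, and the longest segment per
#' population, plus a cohort row.
#'
#' @param roh_set a `roh_set`.
#' @param dataset optional `genotype_dataset` supplying the sample table.
#' @return data.frame with one row per population and an `ALL` row.
#' @export
roh_summary <- function(roh_set, dataset = NULL) {
  samples <- roh_set_samples(roh_set, dataset)
  pops <- sort(unique(samples$population))
  rows <- lapply(pops, function(pp) {
    n_ind <- sum(samples$population == pp)
    s <- roh_set[roh_set$population == pp, , drop = FALSE]
    data.frame(population = pp, n_individuals = n_ind, n_segments = nrow(s),
               mean_roh_per_individual = nrow(s) / n_ind,
               mean_length_mb = if (nrow(s)) mean(s$length_bp) / 1e6 else NA_real_,
               longest_mb = if (nrow(s)) max(s$length_bp) / 1e6 else NA_real_,
               n_with_roh = length(unique(s$sample_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  all_row <- data.frame(
    population = "ALL", n_individuals = nrow(samples),
    n_segments = nrow(roh_set),
    mean_roh_per_individual = nrow(roh_set) / nrow(samples),
    mean_length_mb = if (nrow(roh_set)) mean(roh_set$length_bp) / 1e6 else NA_real_,
    longest_mb = if (nrow(roh_set)) max(roh_set$length_bp) / 1e6 else NA_real_,
    n_with_roh = length(unique(roh_set$sample_id)),
    stringsAsFactors = FALSE)
  rbind(out, all_row)
}

#' Per-chromosome segment counts and ROH coverage
#'
#' Coverage of a chromosome in a population is the summed segment length
#' over all individuals divided by (chromosome SNP span x number of
#' individuals), in `[0, 1]`.
#'
#' @param roh_set a `roh_set`.
#' @param dataset the `genotype_dataset` (supplies chromosome spans).
#' @param by_population also return per-population rows.
#' @return data.frame: `population` ("ALL" for the cohort), `chrom`,
#'   `n_segments`, `coverage`.
#' @export
chrom_counts_and_coverage <- function(roh_set, dataset,
                                      by_population = TRUE) {
  spans <- chrom_spans(dataset$snps)
  spans$span <- spans$last_bp - spans$first_bp
  samples <- dataset$samples
  groups <- c(list(ALL = samples$sample_id),
              if (by_population)
                split(samples$sample_id, samples$population))
  rows <- lapply(names(groups), function(gn) {
    ids <- groups[[gn]]
    s <- roh_set[roh_set$sample_id %in% ids, , drop = FALSE]
    cnt <- table(factor(as.character(s$chrom), levels = spans$chrom))
    covlen <- tapply(s$length_bp, factor(as.character(s$chrom),
                                         levels = spans$chrom), sum)
    covlen[is.na(covlen)] <- 0
    data.frame(population = gn, chrom = spans$chrom,
               n_segments = as.integer(cnt),
               coverage = as.numeric(covlen) / (spans$span * length(ids)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
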