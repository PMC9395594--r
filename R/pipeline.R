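#' Pipeline configuration
#'
#' One declarative object holding every stage's parameters with the standard
#' replication defaults, so a default run needs no extra flags.
#'
#' @param input_prefix path prefix of the genotype files (without
#'   extension).
#' @param input_format `"ped"` (PED/MAP) or `"bed"` (BED/BIM/FAM).
#' @param qc a [qc_params()] object.
#' @param roh a [roh_params()] object.
#' @param scheme a [length_class_scheme()].
#' @param ne an [ne_params()] object.
#' @param island_thresholds incidence thresholds scanned for islands.
#' @param min_island_snps minimum SNPs per island.
#' @param prune a [prune_params()] object.
#' @param ibs_cutoff relatedness cutoff for [remove_related()].
#' @param l_auto_override F_ROH denominator in bp, or `NULL` for the
#'   data-derived span.
#' @param out_dir output directory for the report tables.
#' @param seed integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_prefix, input_format = c("ped", "bed"),
                            qc = qc_params(), roh = roh_params(),
                            scheme = length_class_scheme(),
                            ne = ne_params(),
                            island_thresholds = c(0.7, 0.5, 0.2),
                            min_island_snps = 10,
                            prune = prune_params(), ibs_cutoff = 0.65,
                            l_auto_override = NULL, out_dir = NULL,
                            seed = 1) {
  input_format <- match.arg(input_format)
  stopifnot(all(island_thresholds > 0), all(island_thresholds <= 1))
  structure(list(input_prefix = input_prefix, input_format = input_format,
                 qc = qc, roh = roh, scheme = scheme, ne = ne,
                 island_thresholds = island_thresholds,
                 min_island_snps = min_island_snps, prune = prune,
                 ibs_cutoff = ibs_cutoff, l_auto_override = l_auto_override,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Keys mirror the [pipeline_config()] arguments; nested blocks (`qc`,
#' `roh`, `ne`, `prune`, `scheme`) hold the corresponding constructor
#' arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  pipeline_config(
    input_prefix = y$input_prefix,
    input_format = if (is.null(y$input_format)) "ped" else y$input_format,
    qc = build(qc_params, y$qc),
    roh = build(roh_params, y$roh),
    scheme = build(length_class_scheme, y$scheme),
    ne = build(ne_params, y$ne),
    island_thresholds =
      if (is.null(y$island_thresholds)) c(0.7, 0.5, 0.2)
      else unlist(y$island_thresholds),
    min_island_snps =
      if (is.null(y$min_island_snps)) 10 else y$min_island_snps,
    prune = build(prune_params, y$prune),
    ibs_cutoff = if (is.null(y$ibs_cutoff)) 0.65 else y$ibs_cutoff,
    l_auto_override = y$l_auto_override,
    out_dir = y$out_dir,
    seed = if (is.null(y$seed)) 1 else y$seed)
}

write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' QC, ROH detection, length-class and per-population/per-chromosome
#' summaries, inbreeding coefficients and their correlation, LD-decay Ne
#' trajectories, per-population incidence tracks and ROH islands at each
#' configured threshold, LD pruning, relatedness removal and PCA. When
#' `out_dir` is set, every table is written tab-separated together with a
#' JSON run manifest. Identical config and input give identical outputs.
#' Cross-table consistency (class counts vs. segment total, summary means
#' vs. totals) is asserted and a violation aborts the run.
#'
#' @param config a [pipeline_config()] object.
#' @return A list of class `report_bundle` with elements `qc_report`,
#'   `dataset`, `roh`, `class_counts`, `roh_summary`, `chrom_table`,
#'   `froh_class`, `inbreeding`, `correlation`, `ne`, `incidence`,
#'   `islands`, `pruned_snps`, `pca`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t0 <- Sys.time()
  raw <- if (config$input_format == "ped")
    read_ped_map(paste0(config$input_prefix, ".ped"),
                 paste0(config$input_prefix, ".map"))
  else
    read_bed_bim_fam(paste0(config$input_prefix, ".bed"),
                     paste0(config$input_prefix, ".bim"),
                     paste0(config$input_prefix, ".fam"))

  qc <- apply_qc(raw, config$qc)
  ds <- qc$dataset

  roh <- detect_roh(ds, config$roh)
  class_counts <- classify_lengths(roh, config$scheme)
  summ <- roh_summary(roh, ds)
  chrom_tab <- chrom_counts_and_coverage(roh, ds)

  total_from_classes <-
    as.numeric(class_counts$Total[class_counts$class == "Total"])
  if (total_from_classes != nrow(roh))
    stop("consistency failure: class counts total ", total_from_classes,
         " != segment count ", nrow(roh))
  ms <- summ[summ$population == "ALL", ]
  if (abs(ms$mean_roh_per_individual - nrow(roh) / nrow(ds$samples)) > 1e-9)
    stop("consistency failure: cohort mean ROH per individual")

  l_auto <- if (is.null(config$l_auto_override)) l_auto_bp(ds)
            else config$l_auto_override
  inb <- inbreeding_table(ds, roh, l_auto)
  fclass <- froh_by_class(roh, l_auto, config$scheme, dataset = ds)
  corr <- froh_fhom_correlation(inb)

  ne <- ne_trajectory(ds, config$ne)

  pops <- sort(unique(ds$samples$population))
  tracks <- lapply(pops, function(pp) snp_incidence(roh, ds, pp))
  names(tracks) <- pops
  islands <- do.call(rbind, lapply(config$island_thresholds, function(th) {
    isl <- do.call(rbind, lapply(tracks, call_islands,
                                 threshold_fraction = th,
                                 min_island_snps = config$min_island_snps))
    if (is.null(isl) || !nrow(isl)) return(NULL)
    cbind(threshold = th, isl)
  }))
  if (is.null(islands))
    islands <- data.frame(threshold = numeric(0), population = character(0),
                          chrom = character(0), start_bp = numeric(0),
                          end_bp = numeric(0), n_snps = integer(0),
                          length_mb = numeric(0),
                          peak_incidence_pct = numeric(0))
  rownames(islands) <- NULL

  kept <- ld_prune(ds, config$prune)
  pruned <- subset_dataset(ds, snps = kept)
  unrelated <- remove_related(pruned, config$ibs_cutoff)
  k <- min(10, nrow(unrelated$samples) - 1)
  pca <- pca_genotypes(unrelated, k)

  manifest <- list(
    seed = config$seed, input_prefix = config$input_prefix,
    input_format = config$input_format,
    n_samples_in = nrow(raw$samples), n_snps_in = nrow(raw$snps),
    n_snps_qc = nrow(ds$snps), n_segments = nrow(roh),
    l_auto_bp = l_auto,
    n_snps_pruned = length(kept),
    n_samples_unrelated = nrow(unrelated$samples),
    island_thresholds = config$island_thresholds,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = as.character(getRversion()))

  bundle <- structure(list(
    qc_report = qc$report, dataset = ds, roh = roh,
    class_counts = class_counts, roh_summary = summ,
    chrom_table = chrom_tab, froh_class = fclass, inbreeding = inb,
    correlation = corr, ne = ne, incidence = tracks, islands = islands,
    pruned_snps = ds$snps$snp_id[kept], pca = pca, manifest = manifest),
    class = "report_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_tsv(qc$report$stages, od, "qc_stages.tsv")
    write_tsv(qc$report$removed, od, "qc_removed.tsv")
    seg_out <- data.frame(sample = roh$sample_id, population = roh$population,
                          chrom = roh$chrom, start_bp = roh$start_bp,
                          end_bp = roh$end_bp, n_snps = roh$n_snps,
                          length_mb = segment_length_mb(roh$start_bp,
                                                        roh$end_bp))
    write_tsv(seg_out, od, "roh_segments.tsv")
    write_tsv(class_counts, od, "roh_class_counts.tsv")
    write_tsv(summ, od, "roh_summary.tsv")
    write_tsv(chrom_tab, od, "roh_chromosomes.tsv")
    write_tsv(fclass$population_summary, od, "froh_by_class.tsv")
    write_tsv(inb, od, "inbreeding.tsv")
    write_tsv(corr, od, "froh_fhom_correlation.tsv")
    write_tsv(ne, od, "ne_trajectory.tsv")
    write_tsv(make_manhattan_table(tracks), od, "incidence_manhattan.tsv")
    isl_out <- if (nrow(islands))
      data.frame(threshold = islands$threshold,
                 population = islands$population,
                 position = sprintf("%s:%s:%s", islands$chrom,
                                    format(islands$start_bp, scientific = FALSE,
                                           trim = TRUE),
                                    format(islands$end_bp, scientific = FALSE,
                                           trim = TRUE)),
                 n_snp = islands$n_snps, length_mb = islands$length_mb)
    else data.frame(threshold = numeric(0), population = character(0),
                    position = character(0), n_snp = integer(0),
                    length_mb = numeric(0))
    write_tsv(isl_out, od, "roh_islands.tsv")
    if (nrow(islands))
      islands_to_bed(islands, file.path(od, "roh_islands.bed"))
    writeLines(bundle$pruned_snps, file.path(od, "pruned_snps.txt"))
    write_tsv(pca$coordinates, od, "pca_coordinates.tsv")
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

#' Long-format incidence table for Manhattan plots
#'
#' One row per (population, SNP) with the incidence percentage and a
#' cumulative genome coordinate (strictly increasing across chromosome
#' blocks) for plotting.
#'
#' @param incidence_tracks named list of `incidence_track` objects.
#' @return data.frame: `population`, `chrom`, `bp_pos`, `cum_bp`,
#'   `incidence_pct`.
#' @export
make_manhattan_table <- function(incidence_tracks) {
  if (!length(incidence_tracks))
    return(data.frame(population = character(0), chrom = character(0),
                      bp_pos = numeric(0), cum_bp = numeric(0),
                      incidence_pct = numeric(0)))
  out <- lapply(names(incidence_tracks), function(pp) {
    tr <- incidence_tracks[[pp]]
    chroms <- unique(tr$chrom)
    maxes <- vapply(chroms, function(ch) max(tr$bp_pos[tr$chrom == ch]),
                    numeric(1))
    offset <- stats::setNames(c(0, cumsum(maxes))[seq_along(chroms)], chroms)
    data.frame(population = pp, chrom = tr$chrom, bp_pos = tr$bp_pos,
               cum_bp = tr$bp_pos + offset[tr$chrom],
               incidence_pct = tr$incidence_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
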