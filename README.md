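# rohscape

Runs of homozygosity (ROH), genomic inbreeding and effective population
size (Ne) from diploid autosomal SNP-array genotypes.

When two copies of a chromosomal segment descend from a single ancestral
copy, the individual is homozygous along that whole stretch. Such runs of
homozygosity are the genomic footprint of inbreeding: their total length
measures an individual's autozygosity (F_ROH), their length distribution
dates the inbreeding (long runs are recent, short runs ancient), and
regions where many individuals of a population are simultaneously in ROH
("ROH islands") are candidate targets of selection. Independently, the
decay of linkage disequilibrium (LD) with recombination distance encodes
the historical effective population size. `rohscape` implements this whole
workflow for PLINK-format genotype panels, together with a forward-in-time
Wright-Fisher simulator that generates panels with *known* inbreeding,
demography and implanted islands so every estimator can be validated
against ground truth.

## What the package provides

- **Genotype I/O** — PLINK text (PED/MAP) and binary (BED/BIM/FAM) readers
  and writers around a validated in-memory `genotype_dataset` (dosage
  matrix 0/1/2/NA counting the B allele).
- **Quality control** — `apply_qc()`: autosome restriction, SNP call rate,
  minor allele frequency, and an exact Hardy-Weinberg test, applied in a
  fixed, logged order.
- **ROH calling** — `detect_roh()`: a two-phase sliding-window caller
  (window smoothing, then run building with gap splitting and per-run
  constraints), plus length-class tables, per-population summaries and
  per-chromosome coverage.
- **Inbreeding** — `compute_fhom()` (excess-homozygosity F_HOM),
  `compute_froh()` (F_ROH = L_ROH / L_AUTO), class-wise and
  chromosome-wise partitions, and the F_ROH/F_HOM correlation.
- **Ne trajectories** — `ne_trajectory()`: binned genotypic r² by
  recombination distance, sample-size corrected, mapped to Ne at
  t = 1/(2c) generations.
- **ROH islands** — `snp_incidence()` and `call_islands()`: per-SNP ROH
  incidence tracks and threshold-based island calls, with BED export.
- **Population structure** — greedy windowed LD pruning, identity-by-state
  matrices, relatedness filtering and Patterson-scaled PCA.
- **Synthetic data** — `simulate_wright_fisher()` (recombination, step
  demographies), `simulate_pedigree_inbreeding()` (full-sib, half-sib,
  selfing-like, outbred designs with known expected F) and
  `implant_island()`.
- **Pipeline** — `run_pipeline()` orchestrates QC → ROH → inbreeding → Ne
  → islands → structure from a single (optionally YAML) configuration and
  writes a directory of TSV/BED/JSON outputs; a thin CLI lives at
  `inst/cli/rohscape.R`.

## Worked example

```r
library(rohscape)

sim <- simulate_wright_fisher(sim_params(
  n_autosomes = 2, chrom_length_bp = 6e7, n_snps = 1200,
  sample_sizes = c(HERD_A = 20, HERD_B = 20),
  ne_trajectory = data.frame(generation = 1, ne = 80),
  n_generations = 60, missing_rate = 0.01, seed = 42))

qc <- apply_qc(sim$dataset, qc_params())
qc$report
#> QC report (40 samples):
#>      stage snps_before snps_after
#>   autosome        1071       1071
#>  call_rate        1071       1062
#>        maf        1062       1005
#>        hwe        1005        986
#> 85 SNPs removed in total

rs <- detect_roh(qc$dataset, roh_params(window_snps = 20,
                                        min_snps_in_roh = 20,
                                        max_missing_in_roh = 2))
roh_summary(rs)
#>   population n_individuals n_segments mean_roh_per_individual mean_length_mb
#> 1     HERD_A            20         74                     3.7           5.26
#> 2     HERD_B            20         98                     4.9           5.46
#> 3        ALL            40        172                     4.3           5.38

classify_lengths(rs, length_class_scheme(c(1, 5, 10, 20, 40)))
#>     class HERD_A HERD_B Total
#> 1   1-5Mb     49     64   113
#> 2  5-10Mb     17     21    38
#> 3 10-20Mb      6     12    18
#> 4 20-40Mb      2      1     3
#> 5   >40Mb      0      0     0
#> 6   Total     74     98   172

inb <- inbreeding_table(qc$dataset, rs)
froh_fhom_correlation(inb)
#>   population  n correlation
#> 1     HERD_A 20       0.786
#> 2     HERD_B 20       0.803

head(ne_trajectory(qc$dataset, ne_params(n_bins = 12)), 3)
#>   population  t c_morgans mean_r2_adj  ne n_pairs
#> 1     HERD_A 13    0.0384      0.0554 111    1664
#> 2     HERD_A 14    0.0351      0.0679  98    1715
#> 3     HERD_A 16    0.0318      0.0694 105    1670
```

The simulated truth (Ne = 80) is recovered by the LD trajectory, and
F_ROH tracks F_HOM across individuals.

Real data enter through `read_ped_map()` / `read_bed_bim_fam()`, or via
the pipeline:

```r
cfg <- pipeline_config(input_prefix = "cohort", input_format = "bed",
                       out_dir = "results")
bundle <- run_pipeline(cfg)
```

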