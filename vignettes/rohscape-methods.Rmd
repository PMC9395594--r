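---
title: "Methods and design decisions in rohscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions in rohscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical methods implemented by `rohscape`,
the rationale behind each default parameter, and the package's known
limitations. All defaults are configurable; the defaults describe the
workflow the package is tuned for — medium-density SNP-array panels
(tens of thousands of markers) genotyped on livestock- or
wildlife-scale cohorts (tens of individuals per population).

## Data model and PLINK dialects

The central object is a `genotype_dataset`: a SNP map (chromosome, id,
genetic and physical position, alleles A/B), a sample table (id,
population), and an integer dosage matrix with samples in rows and SNPs in
columns. Dosage counts copies of the B allele: 0 = homozygous A,
1 = heterozygous, 2 = homozygous B, `NA` = missing. The constructor
enforces contiguous chromosome blocks and sorted physical positions, so
every downstream algorithm may assume an ordered map.

Two PLINK 1 dialects are supported. Binary BED/BIM/FAM preserves allele
roles exactly: BIM allele 1 is the counted (B) allele, and the SNP-major
two-bit codes are decoded as 00 = homozygous allele 1 (dosage 2),
01 = missing, 10 = heterozygous, 11 = homozygous allele 2 (dosage 0).
Text PED/MAP carries no allele-role metadata, so `read_ped_map()`
normalizes deterministically: the lexicographically smaller observed
allele code becomes A and the larger becomes B; for monomorphic SNPs the
unseen allele is recorded as `"0"` and the dosage counts the absent minor
allele (so a monomorphic column reads back as all zeros). Binary
round-trips are exact; text round-trips are exact up to this monomorphic
normalization.

## Quality control

`apply_qc()` applies four filters in a fixed, logged order:

1. autosome restriction (default chromosomes 1–29, the bovid autosome
   count; set `n_autosomes` for other karyotypes),
2. SNP call rate — removed when below 0.95,
3. minor allele frequency — removed when below 0.05,
4. Hardy–Weinberg equilibrium — removed when the exact-test p-value is
   below 1e-5.

The order matters (a SNP failing several rules is attributed to the first
stage that removes it) and is therefore fixed and reported in the QC log,
together with every removed SNP and its reason.

The HWE test is the exact conditional test: given the minor-allele count,
the probability of each possible heterozygote count is computed by an
upward recurrence (`P(h+2)/P(h) = 4·n_AA·n_BB / ((h+1)(h+2))`), and the
p-value sums all outcomes no more probable than the observed one (with a
relative tolerance of 1e-9 so mathematically tied outcomes are included).
The exact test is the default because array QC routinely meets genotype
counts where the chi-square approximation is unreliable; a chi-square
variant (`hwe_chisq_p()`) is provided for comparison. The test suite
verifies the exact test against an independent log-multinomial
enumeration for every count triple up to n = 30.

## ROH calling

`detect_roh()` implements a two-phase sliding-window caller.

*Phase 1 (window smoothing).* Every window of `window_snps` consecutive
same-chromosome SNPs is labelled homozygous if it contains at most
`max_het_in_roh` heterozygotes and at most `max_missing_in_roh` missing
calls. Each SNP receives the fraction of overlapping windows that are
homozygous and is flagged when that fraction exceeds
`window_hit_fraction`.

*Phase 2 (run building).* Maximal stretches of flagged SNPs become
candidate runs; a run is split wherever the physical gap between adjacent
SNPs exceeds `max_gap_bp`; candidates violating the per-run constraints
(heterozygote count, missing count, minimum SNPs, minimum length) are
discarded. Segment bounds are the first and last SNP positions, and
segment length is `end − start`.

Defaults: window 50 SNPs, minimum 50 SNPs and 1 Mb per run, 0
heterozygotes, at most 5 missing calls, 1 Mb maximum gap, hit fraction
0.05. Zero tolerated heterozygotes matches the strict definition of a
homozygous segment at array density; the window size and minimum-run
thresholds guard against chance stretches of homozygosity at ~20–50
SNPs/Mb densities.

Two properties are worth recording:

- In the regime `max_het = 0`, non-binding `max_missing`,
  `window_snps ≤ min_snps_in_roh` and `window_hit_fraction < 1/window`,
  the caller is provably equivalent to a brute-force scanner that
  enumerates every maximal heterozygote-free stretch. The test suite
  exploits this for randomized oracle comparison.
- Counts are monotone in `min_length_bp` and `min_snps_in_roh`
  (tightening never adds segments) but **not** in `max_het_in_roh`:
  loosening the heterozygote tolerance merges flagged stretches into
  longer candidate runs whose accumulated heterozygote count can then
  violate the per-run cap, discarding the merged run entirely. This is an
  inherent feature of two-phase window callers, not a bug.

Reported lengths round half-up to 2 decimals in Mb
(`segment_length_mb()`), with a 1e-9 guard so exact halves round upward
despite binary floating point. Length classes default to 1–5, 5–10,
10–20, 20–40 and >40 Mb, left-closed (a 5.00 Mb segment is in 5–10 Mb).

## Inbreeding coefficients

`compute_fhom()` estimates inbreeding from the excess of homozygous
genotypes:

F_HOM = (O_HOM − E_HOM) / (L − E_HOM),

where O_HOM is the individual's observed homozygous count over its L
non-missing SNPs and E_HOM sums, over those SNPs, the expected
homozygosity `1 − 2 p q · n/(n−1)` computed from cohort allele
frequencies with the small-sample correction (n = number of genotyped
allele copies at the SNP). The sign convention makes excess homozygosity
positive: a fully homozygous individual scores 1, and an individual
heterozygous everywhere scores negative.

`compute_froh()` is segment arithmetic: F_ROH = L_ROH / L_AUTO, the
summed autosomal ROH length over the autosomal denominator. By default
L_AUTO is derived from the data as the SNP-covered span (sum over
chromosomes of last-minus-first mapped position) so that F_ROH and the
ROH caller see the same genome; a fixed assembly length can be supplied
instead when comparability across panels matters. Class-wise and
chromosome-wise partitions (`froh_by_class()`, `froh_by_chromosome()`)
decompose the total exactly.

`froh_fhom_correlation()` reports the per-population Pearson correlation
of the two coefficients (NA for groups under 3 samples or without
variance). On simulated cohorts mixing inbred and outbred pedigrees the
two measures correlate strongly, as expected since both estimate realized
autozygosity.

## Effective population size from LD decay

Under drift, the expected squared correlation between loci at genetic
distance c Morgans is approximately `E[r²] = 1/(α + 4 Ne c)`, and SNP
pairs at distance c probe the effective size roughly `t = 1/(2c)`
generations ago. `ne_trajectory()`:

1. computes genotypic (composite, phase-free) r² — the squared Pearson
   correlation of dosages — for all same-chromosome SNP pairs within the
   distance window (default 50 kb – 4 Mb) and above the MAF floor
   (default 0.05);
2. averages r² in equal-width distance bins (default 30) and subtracts
   the 1/n sample-size bias (floored at 1e-6);
3. converts mean physical distance to Morgans at `map_rate` cM/Mb
   (default 1, the usual mammalian average) and inverts the drift
   relation: `Ne = (1/r²_adj − α) / (4c)` at `t = 1/(2c)`.

α = 1 (the drift-only adjustment) is the default; α = 2 is appropriate
when mutation contributes substantially. The resulting trajectory is
diagnostic, not a likelihood estimate: bins are correlated, recent bins
(large distances) are sensitive to the sample-size correction, and
absolute levels inherit the uncertainty of the cM/Mb map rate. The test
suite validates the estimator by recovery: constant-size simulations are
recovered within a factor of two in mid-range bins, and simulated
declines show recent Ne below ancient Ne.

## ROH islands

`snp_incidence()` computes, per population, the fraction of individuals
whose ROH cover each SNP (each individual counted at most once per SNP).
`call_islands()` turns a track into islands: maximal runs of consecutive
same-chromosome SNPs with incidence strictly above the threshold, kept
when they span at least `min_island_snps` SNPs (default 10). Thresholds
are deliberately explored as a ladder (e.g. 0.7, 0.5, 0.2 in the
pipeline): high thresholds often yield nothing in diverse populations,
and the islands that appear at lower thresholds are nested within them.
`islands_to_bed()` exports 0-based half-open BED intervals for use with
genome-arithmetic tools.

## Population structure utilities

- `ld_prune()` — greedy windowed pruning: within each window (default 50
  SNPs, step 5) pairs above `r2_max` (default 0.5) lose the lower-MAF
  member (ties drop the later position).
- `ibs_matrix()` — mean per-SNP allele sharing `(2 − |d_i − d_j|)/2`
  over jointly non-missing SNPs.
- `remove_related()` — greedily removes one member of each pair above the
  IBS cutoff (the lower-call-rate member; ties remove the
  lexicographically larger id), so results are deterministic.
- `pca_genotypes()` — PCA of the dosage matrix with Patterson scaling
  (center by 2p, scale by `sqrt(2p(1−p))`, mean-impute missing), computed
  by SVD; eigenvalues are verified against a dense eigendecomposition in
  the tests.

## The simulator as ground truth

`simulate_wright_fisher()` is a forward-in-time diploid Wright–Fisher
simulator with recombination: founder haplotype frequencies are drawn
uniformly on (0.05, 0.95); each generation samples parents at the current
effective size (step-function trajectories via `ne_trajectory`), and
gametes recombine with per-interval crossover probabilities from
Haldane's map (`0.5(1 − exp(−2d/100))` for d cM). Each labelled
population drifts independently from the shared founder spectrum.
`simulate_pedigree_inbreeding()` gamete-drops fixed pedigrees over a
simulated founder panel, yielding cohorts with known expected inbreeding
(full-sib 0.25, half-sib 0.125, selfing-like 0.5, outbred 0);
`implant_island()` overwrites a region in a chosen fraction of carriers
with homozygous genotypes, creating a known autozygosity hotspot.

Fixture demography matters: pedigree designs need an *effectively
unrelated* founder panel, so the validation panels use a large founder
Ne over few generations (background autozygosity ~2%); and F_ROH
recovery needs enough marker density for the caller's 50-SNP/1-Mb
minima, so validation panels use ≥ 12 SNPs/Mb. These are properties of
the validation design, chosen a priori from the estimators' operating
assumptions.

## Limitations

- ROH calling is rule-based (detect-by-window), not model-based; no
  HMM/likelihood caller is provided.
- The Ne trajectory is a binned method-of-moments diagnostic without
  confidence intervals; bins share SNP pairs and are not independent.
- The exact HWE test assumes autosomal biallelic genotypes; X-chromosome
  dosage compensation is out of scope (non-autosomes are removed in QC).
- The simulator models unlinked founder frequencies (no ancestral LD
  beyond what drift and recombination generate during the simulated
  generations) and infinite-sites-free biallelic mutation flips at a
  nominal rate.
- PED round-trips cannot preserve the counted allele of monomorphic
  SNPs (see the I/O section); use the binary dialect when allele roles
  must survive.
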