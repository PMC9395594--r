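Package: rohscape
Title: Runs of Homozygosity, Genomic Inbreeding and Effective Population
    Size from SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conservation-genomics toolkit for diploid autosomal SNP-array
    genotypes in PLINK text (PED/MAP) and binary (BED/BIM/FAM) formats.
    Provides marker quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test), sliding-window detection of runs of
    homozygosity (ROH) with per-individual, per-population, per-chromosome
    and length-class summaries, genomic inbreeding coefficients (F_HOM from
    the excess of homozygous genotypes and F_ROH from the autosomal fraction
    covered by ROH), effective population size trajectories from binned
    linkage-disequilibrium decay, detection of ROH islands (autozygosity
    hotspots) from per-SNP ROH incidence, population-structure utilities
    (LD pruning, identity-by-state relatedness filtering, principal
    component analysis), and a forward-in-time Wright-Fisher simulator with
    recombination that generates genotype panels with known inbreeding,
    demography and implanted autozygous islands for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
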