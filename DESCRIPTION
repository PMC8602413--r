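Package: introscan
Title: Introgression Scans and Domestication Selection Signatures for Ovis Genotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-based detection of interspecific introgression and
    domestication selection signatures from multi-population biallelic SNP
    genotypes. Implements site filtering (missingness, minor allele
    frequency, heterozygote-excess exact test), outgroup allele
    polarization, sliding-window nucleotide diversity, dxy and Hudson FST,
    an LD r-squared decay curve, Patterson's D and f3 with weighted block
    jackknife, the fd window scan of Martin et al. with
    Benjamini-Hochberg FDR control and merging of significant windows into
    introgressed tracts, a pi-ratio by FST top-decile selection scan with
    gene-overlap enrichment, an incomplete-lineage-sorting tract-length
    probability model, a delta-delta-CT qPCR relative copy-number caller,
    and a seeded Balding-Nichols cohort simulator with planted
    introgression tracts and selective sweeps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
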