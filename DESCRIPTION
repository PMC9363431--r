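Package: repadapt
Title: Genome Scans for Repeated Local Adaptation Across Altitudinal Transects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects repeated (parallel) local adaptation across replicated
    population transects from biallelic genotype data. Implements windowed
    Hudson Fst and population branch statistics (PBS) with z-normalisation,
    nucleotide diversity, Tajima's D and absolute divergence (Dxy) tracks,
    high-differentiation-region (HDR) calling with buffered interval merging,
    cross-transect sharing classification with random-interval permutation
    nulls and block-jackknife confidence intervals, selection-signature
    enrichment against permuted interval extrema, global and local PCA with
    altitude-association models and inversion karyotype clustering, and
    windowed f_dM excess-allele-sharing scans for standing variation and
    adaptive introgression. A Balding-Nichols allele-frequency simulator with
    planted sweeps, shared standing variants, introgression tracts and an
    inversion-like haplotype block makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
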