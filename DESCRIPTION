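Package: zeapop
Title: Population Genomics of Introgression and Selective Sweeps in
    Helicoverpa zea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed ABBA-BABA (D and fd-hat) statistics for detecting
    interspecific introgression, Hudson FST / dxy / nucleotide diversity in
    sliding windows, isolation-by-distance regression on linearized FST,
    a composite-likelihood selective-sweep scan on the unfolded site
    frequency spectrum with selection-coefficient estimation, deterministic
    single-locus selection-trajectory modelling and random-search fitting of
    selection and dominance coefficients, VCF-level variant quality control
    (Hardy-Weinberg exact-test and Z-heterozygosity association filters),
    and coding-variant effect classification. Includes synthetic genotype
    generators (neutral site-frequency-spectrum backgrounds, sweep-distorted
    spectra, Balding-Nichols structured demes, donor haplotype tracts, and
    noisy allele-frequency time series) so every stage of the analysis can
    be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
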