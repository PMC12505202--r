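Package: madcpipe
Title: Mid-Density Targeted Amplicon Genotyping from MADC Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and analysis of mid-density targeted-amplicon
    (DArTag-style) genotyping data distributed as missing allele discovery
    count (MADC) files. Provides parsing and windowed deduplication of
    target-SNP read counts, read-threshold missingness and polymorphism QC,
    allele-ratio principal component analysis, reference-standardized
    ploidy inference from B-allele frequency peaks, beta-binomial allele
    dosage calling with population ("norm") and biparental ("f1") priors,
    sub-genome classification of loci in interspecific hybrids, two-point
    recombination-fraction and linkage-group utilities with physical-order
    repositioning heuristics, even-spacing marker panel design, and a
    synthetic read-count generator producing mixed-ploidy cohorts, F1
    crosses and two-sub-genome hybrids with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
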