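Package: fjordcod
Title: Genome Scans, Inversion Karyotyping and Telemetry-Based Behavioural
    Analysis for Sympatric Fish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sympatric population divergence in marine
    fish from whole-genome SNP data and acoustic telemetry. Provides a
    genotype and telemetry simulator with known ground truth, VCF-based
    genotype loading and filtering (depth and quality masking, missingness,
    minor-allele and heterozygote-excess site filters, LD pruning),
    nonoverlapping windowed genome scans (Weir-Cockerham FST, dxy, fixed
    differences, nucleotide diversity, LD r2), chromosomal-inversion
    karyotype calling from region-restricted PCA with bootstrap
    arrangement-frequency tests and Hardy-Weinberg exact tests, acoustic
    telemetry processing (centres of activity, diel vertical migration,
    kernel home ranges, fate classification), and linear mixed and selection
    gradient model ladders with AIC-based selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
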