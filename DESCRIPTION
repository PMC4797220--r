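Package: cldla
Title: Combined Linkage and Linkage-Disequilibrium Mapping of Recessive
    Disease Loci from Pedigreed SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component QTL mapping for recessive disorders in
    livestock populations. Implements locus identity-by-descent estimation
    from phased marker haplotypes in sliding windows, conversion to
    diplotype relationship matrices, REML likelihood-ratio scans with
    Bonferroni chi-square thresholds and 2-LOD support intervals,
    case-control homozygosity mapping with phenocopy diagnostics,
    common-haplotype extraction, carrier-concordance filtering of sequence
    variants, and population allele-frequency monitoring with
    carrier-mating risk. A gene-dropping simulator with exact
    founder-segment identity-by-descent truth generates pedigreed SNP
    panels with a planted recessive locus so that the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
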