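Package: meiotrace
Title: Haplotype-Transmission HMM for Embryo Aneuploidy and Crossover Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint inference of chromosome copy number, parental origin,
    meiotic error class and crossover recombination events from SNP-array
    B-allele frequencies of trophectoderm biopsies, using a hidden Markov
    model over transmitted parental haplotypes. Includes transmission-based
    phasing of parents from sibling embryos, a meiosis simulator with
    configurable mis-segregation modes, cohort phenotype statistics
    (crossover counts, hotspot occupancy, sequence context, binomial
    overdispersion, cross-chromosome intraclass correlation), and a
    selection-coefficient proxy model of lifetime euploid-embryo production.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
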