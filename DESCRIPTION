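Package: strpop
Title: Forensic STR Population Genetics with Theta-Corrected Match Probabilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic short tandem repeat (STR) population studies:
    reading and writing genotype and allele-frequency tables for autosomal and
    X-chromosomal loci, simulation of structured populations under the
    Balding-Nichols model, per-locus and combined forensic parameters
    (heterozygosities, PIC, match probability, powers of discrimination and
    exclusion, paternity index, and the X-chromosomal mean exclusion chance
    family defined by an exact pedigree-enumeration engine), multi-allelic
    Hardy-Weinberg exact tests (Monte Carlo and complete enumeration),
    two-locus linkage-disequilibrium tests for haplotypic and phase-unknown
    data, pairwise Weir-Cockerham F_ST with permutation p-values, principal
    coordinates analysis, and auditing of subpopulation-corrected random match
    probabilities against cognate and non-cognate frequency databases via the
    log10 RMP-ratio d statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
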