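Package: haploSweep
Title: Long-Haplotype Selection Scans and GWAS Catalogue Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hard selective sweeps in phased haplotype panels by
    locating uncharacteristically long haplotype forms on a grid of carrier
    frequencies and ranking them genome-wide with empirical p-values (the
    haploPS-style score). Evaluates GWAS index SNPs against the resulting
    selection regions: region overlap, presence of the risk allele on the
    selected haplotype form, ancestral/derived status against an outgroup
    allele, and locus-specific FST between populations; a haplotype
    similarity index separates shared-origin from convergent sweeps.
    Ships a mosaic haplotype simulator with implantable sweeps and
    Balding-Nichols population divergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
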