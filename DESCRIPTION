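Package: sweepcnvr
Title: Selection-Signature and Copy-Number Differentiation Scans for
    Population Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed selection-signature scans (nucleotide diversity,
    Tajima's D, Weir-Cockerham FST, iHS, and a SweepFinder-style composite
    likelihood ratio) over phased SNP genotypes, together with a
    multi-caller structural-variant consensus pipeline that builds
    copy-number-variable regions (CNVRs) and scans them for
    group-differentiated copy number with the VST statistic. Includes a
    forward Wright-Fisher simulator with selection and pseudo-caller CNV
    call-set generators so the whole analysis chain can be exercised and
    validated on synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
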