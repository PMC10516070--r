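Package: nearcoding
Title: Prioritisation of Promoter and UTR Variants in Dominant Disease Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A framework for identifying potentially disease-causing variants
    in the 'near-coding' regions of known dominant disease genes: proximal
    promoters defined from candidate cis-regulatory elements, UTR exons, and
    UTR introns. Provides region construction with CDS subtraction,
    sequence-level annotation of 5'UTR translational effects (uAUG gain/loss,
    uSTOP loss, uFrameshift, Kozak context), 3'UTR polyadenylation-signal
    scanning, overlay annotations (IRES, miRNA sites, dORFs, RBP binding loss,
    TFBS binding-change aggregation), an arm-aware region-specific
    prioritisation cascade, and matched case-control burden testing with
    exact tests, Bonferroni correction and iterative power estimation.
    Includes seeded synthetic-data generators so the full pipeline is
    testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb
Config/testthat/edition: 3
RoxygenNote: 7.3.3
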