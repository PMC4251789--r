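Package: ascnscan
Title: Allele-Specific Copy-Number Association Scanning for Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cohort-level analysis of absolute allele-specific somatic
    copy-number profiles. Classifies segment-level alteration types (absolute
    and ploidy-relative gain and loss, homozygous deletion, high gain, focal
    events, loss of heterozygosity), builds a cohort-wide breakpoint-union
    segment grid, scans the genome for alterations associated with tumour
    dissemination using Fisher's exact test with conditional
    maximum-likelihood odds ratios, scores per-sample evidence of whole-genome
    duplication from autosome-arm median states, classifies chromosomal
    instability, and runs clinical contingency-table tests. Includes a seeded
    synthetic-cohort generator emulating allele-specific caller output for
    quiet near-diploid and CNA-rich genome classes with planted
    group-differential lesions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
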