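Package: clonetracker
Title: Clonal Evolution Tracking from Serial Tumor Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tracks tumor clonal evolution across serially collected samples
    from a single case. Applies depth and allele-frequency competence filters
    to somatic variant tables, harmonizes variant allele fractions into a
    variants-by-samples matrix, partitions variants into mutually exclusive
    subclone-defining sets and detects clonal replacement events, computes
    tumor/normal log2 copy-number ratios with focal-amplification calling and
    absolute copy estimation, tests gene-fusion breakpoint concordance across
    samples, summarizes per-gene silent-mutation fractions from a reference
    mutation catalog for driver/passenger assessment, and prioritizes
    amplified overexpressed candidate genes by RPKM fold change. A synthetic
    serial-cohort generator with known clonal truth makes every stage testable
    without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
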