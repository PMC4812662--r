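Package: cnvpol
Title: Consensus Calling, Polarization and Mechanism Classification of
    Copy Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for population copy-number-variant (CNV)
    analysis from multi-caller call sets: per-accession consensus merging under
    a reciprocal-overlap criterion, breakpoint refinement, population-level
    merging, ancestral-state polarization against an outgroup genome through
    synteny-anchor projection, breakpoint-signature classification of formation
    mechanisms (NAHR, NHR, MEI, VNTR), gene-impact and population-sharing
    annotation, hypergeometric term enrichment, and origin inference for
    non-co-linear CNV genes.  Includes a synthetic-genome simulator that
    implants mechanism-labelled CNVs and emits noisy caller-like call sets, so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
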