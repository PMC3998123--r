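Package: cohortsnv
Title: Subclonal Variant Calling from Cohort-Wide Error Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls clonal and subclonal single-nucleotide variants and
    single-base deletions in large targeted-resequencing cohorts. For every
    sample, site and allele, a leave-one-out aggregate control built from
    all other low-VAF samples defines a strand-specific beta-binomial
    sequencing-error model; a Bayes factor compares the error-only null
    (variant absent on at least one strand) against a two-strand variant
    model, and a per-site mutation-hotspot prior converts it into a
    posterior probability by Bayes' formula. Includes pileup-based count
    extraction from BAM files, VCF output, and a simulation benchmark for
    power and ROC AUC of the caller.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    Biostrings,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
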