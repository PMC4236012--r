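Package: triovar
Title: Somatic SNV Calling from Matched Normal DNA, Tumor DNA and Tumor RNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrated somatic single-nucleotide-variant calling over
    patient-matched normal DNA, tumor DNA and tumor RNA alignments. A lenient
    heuristic detector proposes candidate sites which are then filtered by two
    parallel decision procedures: a DNA-only method over the tumor/normal pair
    and a triple-sample method that additionally requires RNA read support,
    allowing mutations with weak DNA evidence but strong RNA evidence to be
    rescued. Calls from the two methods are merged, subjected to a final
    perfect-read support filter and written as VCF. The package also provides
    a read-level mutation spike-in simulator with truth records, a synthetic
    pileup generator for fully self-contained testing, and a validation-status
    classifier with precision reporting for benchmarking against deep
    resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
biocViews: Software, VariantDetection, SomaticMutation, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
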