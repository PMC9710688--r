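Package: cfdip
Title: Bias-Corrected cfDNA Coverage-Dip Signatures at Genomic Region Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nucleosome-footprint coverage dips in cell-free DNA
    whole-genome sequencing data at user-provided sets of genomic regions
    (for example tissue- or tumor-specific DNase I hypersensitivity sites).
    Reconstructs DNA fragments from paired-end alignments, bins coverage on a
    center-aligned grid shared across regions, regresses out technical biases
    (GC content, di- and trinucleotide composition, mappability), aggregates
    corrected coverage into a per-sample signature profile, fits a parametric
    Gaussian-dip model to derive signature-strength metrics, and tests case
    samples against a control group.  Ships a synthetic-data generator
    (toy genome, region sets, paired-end BAM, mappability track) with a
    recorded truth table so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    xgboost,
    jsonlite,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
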