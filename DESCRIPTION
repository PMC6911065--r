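Package: somaticEnsemble
Title: Multi-Caller Somatic Variant Consensus, Filtering and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-calling consensus stack for tumor-normal whole-genome
    somatic analysis: cross-caller merging of SNV/MNV/indel callsets with
    MNV decomposition and re-constitution, BEDPE-based structural-variant
    merging with reciprocal-overlap matching, panel-of-normals and common
    germline filtering, pileup-based allele-count selection and somatic
    count filters, high-confidence annotation from orthogonal evidence,
    and purity/ploidy adjustment of copy-number log2 ratios. Includes an
    in-silico tumor-normal mixture (purity ladder) simulator, precision/
    recall evaluation with base-level CNV comparison, and a read-level
    trinucleotide mismatch and homopolymer profiler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    IRanges,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
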