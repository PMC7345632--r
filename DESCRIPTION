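Package: miredscan
Title: Detection and Classification of MicroRNA Editing Events from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate RNA editing sites in mature microRNAs from small
    RNA sequencing reads. Reads are adapter-trimmed, quality filtered and
    mapped to pre-miRNA hairpins under a unique-best, at-most-one-mismatch
    rule; per-site substitutions are tested against a Phred-calibrated
    binomial sequencing-error model with Bonferroni correction; surviving
    calls are filtered against known DNA variants and the sequencer-biased
    A-to-C class, classified as canonical or non-canonical and seed or
    non-seed, and summarised across samples and tissues. The package also
    provides a synthetic small RNA read simulator with injected editing
    events and ground-truth tables for validation, flanking-base context
    profiles with proportion tests, trinucleotide enrichment statistics, and
    a seed-match target-overlap statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
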