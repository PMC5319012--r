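Package: splicescout
Title: Detection and Visualization of Alternative Splicing Events from
    Junction Counts and Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects alternative splicing events between sample conditions
    from per-sample splice-junction counts and per-base read coverage.
    Candidate exons are scored by a greedy percent-spliced-in (PSI) statistic
    built from the best inclusion/exclusion junction pair, and independently
    by a per-nucleotide coverage-ratio test against the remaining exon
    groups of the gene. Includes median-of-ratios size-factor normalization,
    automated isoform pre-selection, meta-exon construction from gene
    annotation, tissue-specificity (tau) scoring, static sashimi-style
    coverage/ratio/isoform plots, a seeded synthetic-data generator with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ggplot2,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
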