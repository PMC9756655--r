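Package: cdgmap
Title: Comparative Genomics of c-di-GMP Signaling Genes on Bacterial Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacterial proteins into c-di-GMP-metabolizing enzyme
    groups (GGDEF, EAL, GGDEF_EAL hybrids, HD-GYP) from Pfam-style domain
    architectures, places genes on circular replicons relative to the
    replication origin (ori at 0 percent, terminus at 50 percent), and
    quantifies positional and numerical patterns: circular kernel density
    estimates, two-sample Kolmogorov-Smirnov comparisons (asymptotic and
    exact-permutation), per-genus count summaries and class ratios,
    auxiliary-domain Venn partitions, co-occurrence networks and
    length-threshold analyses, and replicon-class accounting with a
    secondary-chromosome size rule. Includes a GC-skew origin estimator and
    a deterministic synthetic-genome generator with a machine-readable truth
    record so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
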