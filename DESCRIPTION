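Package: domainscape
Title: Comparative Analysis of Repeat-Dense Chromosomal Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A comparative-genomics toolkit for contrasting a repeat-dense
    (heterochromatic) chromosomal domain against a euchromatic reference
    region. Provides repeat-density accounting with class-aware interval
    merging and "Overlapping" reclassification, score filtering and overlap
    attribution of foreign-genome matches, alignment coverage tracks,
    coding-span gene-architecture metrics from the most comprehensive
    isoform, a codon-bias suite (Wright's effective number of codons, the
    codon adaptation index, GC partitions including fourfold-degenerate
    sites), nearest-neighbor melting-temperature and Poisson log-likelihood
    enrichment metagene profiles with spline smoothing, and the supporting
    statistics (Kruskal-Wallis, Dunn post hoc with Holm step-down,
    upper-tail hypergeometric enrichment, Spearman correlation, LOESS with
    cross-validated span). A synthetic-genome generator with exact ground
    truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
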