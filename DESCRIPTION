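Package: florest
Title: Comparative EST Transcriptome Analysis of Flower Sex Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative EST (expressed
    sequence tag) transcriptome analysis between two flower sex types of a
    diploid plant sequenced as two 454-style cDNA libraries from
    near-isogenic lines. Provides flanked gene-region construction, a
    minimal splice-aware EST aligner with identity/coverage acceptance,
    intron-exon junction extraction and five-way alternative-splicing event
    classification (AltD, AltA, AltP, IntronR, ExonS), tag-count digital
    expression testing with the Stekel log-likelihood-ratio R statistic and
    q-values, MISA-style microsatellite (SSR) mining with compound merging
    and motif canonicalization, homopolymer-aware inter-line SNP filtering,
    GO-slim mapping and hypergeometric GO enrichment, plus a synthetic-data
    generator that produces genomes, gene models, EST libraries and truth
    tables exhibiting the structure every downstream stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    methods,
    tibble,
    dplyr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
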