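Package: dreseq
Title: Differential RNA Editing Analysis from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects RNA editing sites from aligned RNA-seq reads under
    quality, depth, alternative-allele and frequency filters; annotates
    sites by genomic region, substitution class (C-to-U, A-to-I) and
    protein-level consequence; tests for differential editing at the site
    and gene level and for differential expression with a negative-binomial
    count model; and integrates the editing and expression layers
    (nine-quadrant classification, Venn overlap, PCA of editing
    frequencies, editing-frequency/expression correlation). Ships a
    synthetic-study generator with planted editing events and truth tables
    so the whole pipeline can be exercised and benchmarked end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    MASS,
    seqinr,
    DESeq2
Config/testthat/edition: 3
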