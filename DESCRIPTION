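Package: tagscan
Title: Duplicated k-mer Signatures in Conserved Non-Coding Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of duplicated, conserved short-motif
    (pentamer) signatures in conserved non-coding elements (CNEs) and scoring
    of their association with tissue-specific gene expression. Builds CNEs
    from pairwise whole-genome alignment blocks (MAF) after removing
    transcribed positions, scans all canonical k-mer classes for duplicate
    conserved occurrences within a distance window, maps CNEs to host or
    nearest flanking genes, and ranks motif-tissue associations with a
    binomial upper-tail enrichment score. Includes annotation-shuffling
    confidence intervals, copy-number and window-size robustness sweeps,
    candidate-enhancer nomination, a synthetic fixture generator that plants
    motif enrichment near genes of a chosen tissue, and a backtracking
    designer for spacer sequences that avoid a forbidden k-mer set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
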