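Package: derseg
Title: Differentially Expressed Region Finding from Base-Resolution RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Identify-then-annotate differential expression analysis for
    RNA-seq. Per-base coverage from bedGraph tracks is modelled with a
    linear regression on log coverage; empirical-Bayes moderated statistics
    are segmented by a three-state hidden Markov model into not-expressed,
    equally-expressed and differentially-expressed regions; candidate
    regions receive permutation-based empirical p-values with
    Benjamini-Hochberg FDR control, and can be annotated against a GTF or
    BED feature reference. Includes a negative-binomial coverage simulator
    with known planted regions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    yaml,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
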