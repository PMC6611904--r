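Package: cismark
Title: Cis-Element Scanning and H3K36me3 Island Enrichment Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking a 7-bp promoter cis-element
    (5'-CGGAAAT-3') to gene-body H3K36me3 chromatin marking. Provides
    strand-aware promoter extraction and exact-pattern element scanning
    with TSS-relative coordinates, SICER-style windowed island calling of
    broad ChIP-seq domains with Poisson significance and Benjamini-Hochberg
    FDR, scaled metagene TSS-to-TES profiles calibrated to input, gene-set
    intersection of element-containing and down-regulated genes, and a
    seeded resampling null (with its analytic hypergeometric comparator)
    testing whether element-containing down-regulated genes are
    preferentially H3K36me3-marked. A synthetic-data module generates
    annotations, promoter sequences with planted elements, ChIP and input
    coverage with planted 5'-biased enrichment, and differential-expression
    tables with a configurable element-to-down-regulation association, so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
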