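Package: homeolocus
Title: Comparative Analysis of Homoeologous Wheat Loci Against Model Grass Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare megabase-scale homoeologous loci of allopolyploid
    wheat (B and D genomes) with orthologous regions of Brachypodium distachyon
    and rice. Implements exact local alignment scoring with Karlin-Altschul
    E-values, reciprocal-best homolog mapping, order-preserving anchor chaining
    to classify genes as collinear or non-collinear, tandem-duplication
    resolution, pseudogene detection with mechanism attribution (transposable
    element insertion, point frameshift, internal deletion, terminal
    truncation), insertion-epoch and rate-ratio inference, EST-based expression
    scoring with exact-match criteria, a simplified core-promoter scan,
    three-dimensional BAC pool design and deconvolution, and scaffold curation
    by end matching. Includes a locus-evolution simulator with a logged event
    history and a deterministic multi-genome fixture generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
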