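Package: toxbiome
Title: Sex-Biased Chemoradiotherapy Hematologic Toxicity and the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking chemoradiotherapy-induced
    hematologic toxicity to gut-microbiome composition and metabolism.
    Grades hematologic adverse events from longitudinal blood counts
    (CTCAE-style lab bands), computes a weighted hematologic toxicity
    index (HTI), and reproduces cohort-table comparisons; computes alpha
    and beta diversity, principal-coordinates ordination, PERMANOVA
    effect sizes, and the Scheirer-Ray-Hare rank test for longitudinal
    diversity; screens features by a LEfSe-style Kruskal-Wallis plus
    effect-size rule and fits MaAsLin-style multivariable linear
    associations with Benjamini-Hochberg correction; builds group-wise
    microbial co-occurrence networks and ranks driver taxa by a
    NetShift-inspired neighbor-shift and betweenness score; and performs
    two-sample Mendelian randomization (instrument selection, LD
    clumping, harmonization with proxies, IVW, MR-Egger, weighted
    median, and sensitivity analyses) from GWAS summary statistics.
    Ships synthetic-data generators with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
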