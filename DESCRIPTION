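Package: adtbgc
Title: Biogeography of Biosynthetic Gene Clusters in Aerodigestive Tract Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying the distribution of
    specialized-metabolite biosynthetic gene clusters (BGCs) across human
    aerodigestive-tract body sites from shotgun metagenomes. Provides a
    catalog data model with category and habitat-source summarization, a
    k-mer pseudoaligner with EM resolution of multi-mapping reads,
    median-of-ratios count normalization, alpha- and beta-diversity
    statistics (Shannon metrics, Bray-Curtis, ANOSIM, NMDS, Ward
    clustering), one-vs-rest negative-binomial Wald enrichment calling,
    ANCOM-style compositional differential abundance, BGC family and RiPP
    core-peptide similarity networks, and a synthetic-study generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ape,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    vegan,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
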