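Package: loadscape
Title: Genetic Load Partitioning, Purging and ROH-Based Inbreeding Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for conservation-genomics analyses of small, inbred
    populations from multi-sample genotype data: hard filtering of
    already-called variants, ancestral-allele polarization with two
    outgroup species, classification of mutations into deleteriousness
    classes (annotation impact categories and GERP conservation scores),
    partitioning of the genetic load into its masked (heterozygous) and
    realized (homozygous-derived) components, population-level
    high-frequency load and purging contrasts with the associated
    nonparametric tests, runs-of-homozygosity based inbreeding
    coefficients (F_ROH) and recent effective-population-size
    reconstruction from ROH length classes, diversity summaries, and a
    neighbor-joining tree on identity-by-state distances. A fully
    labelled synthetic-data generator emulating a three-population
    island study design makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    vcfR,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
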