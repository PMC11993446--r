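Package: gastromicro
Title: Intratumoral Microbiome Decontamination and Analysis for Gastric
    Cancer Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the intratumoral microbiome of gastric
    cancer from host sequencing data. Reads per-sample taxon tables in the
    GATK PathSeq output shape, removes contaminants with an include-list
    strategy that compares taxon prevalence between tumor tissue and
    matched blood using one-sided Fisher exact tests with Storey q-values,
    normalises microbial abundance to microbes per human cell (adjusting
    the human genome size for ploidy and tumor purity), infers microsatellite
    instability status and TCGA-style molecular subtype from mutation
    burden, Epstein-Barr virus load and ploidy, computes Shannon alpha
    diversity and Bray-Curtis beta diversity with sequential PERMANOVA,
    and fits MaAsLin2-style multivariable differential-abundance models
    restricted to PERMANOVA-significant covariates. A synthetic paired
    tumor/blood cohort generator with known ground truth supports testing
    every stage without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
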