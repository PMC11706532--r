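Package: mrkit
Title: Two-Sample Mendelian Randomization and Polygenic Risk Scoring from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for two-sample Mendelian randomization
    (MR) and polygenic risk scoring (PRS) from GWAS summary statistics.
    Provides a canonical per-SNP association table with flexible column
    mapping, stepwise data cleaning with filter reporting, derivation of
    standard errors from p-values and vice versa, coordinate filling from a
    variant map, genome-build liftover via UCSC chain files, a native PLINK 1
    binary fileset reader/writer, LD computation and proxy search, greedy
    p-value-ordered LD clumping, polygenic scoring with allele alignment and
    mean imputation, per-SNP association testing, exposure/outcome
    harmonization with palindromic-SNP resolution and proxy substitution, the
    standard MR estimator family (IVW, MR-Egger, median, mode) with Cochran's
    Q and plot data, and a seed-deterministic parallel MR-PRESSO. A built-in
    simulator generates LD-structured reference panels and two-sample GWAS
    summary statistics under a configurable causal/pleiotropy model so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    parallel
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr
Config/testthat/edition: 3
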