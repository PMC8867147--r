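Package: m6adiff
Title: Differential m6A Modification, Metagene, Motif and 3' End Usage
    Analysis for Direct RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of per-read and per-site tables derived
    from nanopore direct RNA sequencing of two conditions (e.g. wild type
    versus a methyltransferase mutant). Calls replicate-consistent
    differentially methylated (hypomethylated) A-centered sites with a
    two-proportion z-test on modification rates, maps sites onto a
    normalized 5'UTR/CDS/3'UTR metagene axis, summarizes k-mer usage and
    derives a degenerate IUPAC consensus motif with a binomial enrichment
    test, detects alternative polyadenylation shifts from read 3'-end
    usage with Kolmogorov-Smirnov tests and Benjamini-Hochberg control,
    compares poly(A) tail lengths, and associates hypomethylation with
    expression change. Includes a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
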