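Package: aflpimprint
Title: In Silico cDNA-AFLP Fragment Prediction and Imprinted-Gene Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate imprinted genes from cDNA-AFLP
    screens of reciprocal crosses. Simulates the two-enzyme restriction
    digestion and selective amplification of the cDNA-AFLP protocol on
    transcript sequences, predicts capillary fragment sizes, and identifies
    the gene behind an observed transcript-derived fragment (TDF) from its
    primer combination and size. Includes a parent-of-origin caller for
    presence/absence allele tables from reciprocal crosses, an
    endosperm-enrichment ranker for seed tissue expression data, a
    pyrosequencing allele-fraction summarizer, a differentially methylated
    region (DMR) finder for candidate imprinting control regions, and
    seeded synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    dplyr,
    purrr,
    readr,
    rlang,
    rtracklayer,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
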