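Package: heteropeus
Title: Predicting Maize Heterosis from Heterozygous PEUS SNP Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A line-by-tester analysis pipeline for predicting mid-parent and
    better-parent heterosis of grain yield in maize from whole-genome SNP data.
    Reads and quality-filters multi-sample VCFs of homozygous inbred parents,
    classifies SNPs into PEUS categories (promoters, exons, untranslated
    regions, stop codons) from GFF3 gene models, counts heterozygous and
    homozygous PEUS SNPs per cross, computes identity-by-state genetic
    distance, derives heterosis and the line-by-tester analysis of variance
    with Fisher's LSD and Kempthorne combining abilities from plot-level
    yields, and correlates predictors with heterosis. Includes a
    dominance-model simulator that generates genotypes, gene models, designs
    and multi-location yield trials with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
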