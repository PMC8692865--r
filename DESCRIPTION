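Package: spinpop
Title: Population Genetics of Wild and Cultivated Spinach from GBS SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for diploid biallelic SNP panels from
    genotyping-by-sequencing (GBS): a VCF filtering cascade with provenance
    (indels, biallelic, MAF, site quality, genotype depth, missingness), LD
    pruning and SNP density summaries; per-locus and per-group diversity
    statistics (gene diversity, PIC, Na, Ne, h, uh, Shannon's I, windowed
    nucleotide diversity); pairwise differentiation (AMOVA-based PhiPT with a
    permutation null, Weir-Cockerham Fst, Nei's unbiased distance and identity,
    island-model gene flow Nm); maximum-likelihood admixture inference with
    Evanno delta-K model selection, PCA and bootstrap neighbor-joining trees;
    LD decay at an r-squared threshold; and a composite-likelihood
    cross-population selective-sweep scan with window merging into sweep
    regions. Includes a Balding-Nichols synthetic-data generator with
    admixture, injected sweeps, missingness and depth/quality fields so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
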