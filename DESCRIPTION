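Package: flocknet
Title: Within-Breed SNP Diversity, Identity-by-State Networks and
    Mixed-Model Association for Livestock Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diploid biallelic SNP-array genotypes of
    livestock populations: PLINK text (PED/MAP) input and output, marker and
    sample quality control, observed and expected heterozygosity with breed
    and individual inbreeding coefficients, pairwise Weir-Cockerham Fst,
    principal components of the standardized relationship matrix, pairwise
    identity-by-state (IBS) similarity with threshold-to-connectivity network
    construction, betweenness-based hub detection and hub-removal re-analysis,
    standardization of lamb daily weight gain to a 60-day reference, and a
    multi-locus mixed-model genome scan (EMMA-style REML with forward cofactor
    selection and Benjamini-Hochberg FDR). Includes a synthetic-data generator
    (Balding-Nichols breed divergence, Mendelian hub-sire pedigrees, QTL plus
    polygenic phenotypes) so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
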