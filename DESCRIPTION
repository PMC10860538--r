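Package: clonepulse
Title: Clonal Architecture and Immunophenotype Dynamics from Single-Cell
    DNA + Protein Multiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired-timepoint single-cell targeted
    DNA genotyping with simultaneous surface-protein (ADT) readout, as
    produced by droplet amplicon platforms in myeloid malignancies.
    Provides genotype and cell quality control with allele-dropout (ADO)
    estimation from germline heterozygous variants, genotype-identity
    clone calling with ADO-artifact removal and phylogeny reconstruction,
    amplicon-based ploidy and copy-number inference against a wild-type
    diploid baseline, CLR-normalised isotype-denoised immunophenotyping
    with graph clustering and marker-rule annotation, Dirichlet-multinomial
    compositional abundance testing with automatic reference selection,
    paired-timepoint clonal-dynamics classification, and genotype by
    phenotype integration. A synthetic cohort generator with full ground
    truth makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    RANN,
    readr,
    rlang,
    Seurat,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    knitr,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
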