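Package: namgwas
Title: Non-Additive Genome-Wide Association Analysis for Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association analysis of a count phenotype
    (habitual coffee consumption, cups per day) under additive, dominant
    and recessive genotype codings in family-structured cohorts. Provides
    genomic-kinship estimation, a two-step polygenic mixed model with an
    exact generalised-least-squares score test (FASTA/GRAMMAR style),
    model-specific genotype coding and variant filters, fixed-effect
    inverse-variance meta-analysis with genomic control and an
    effective-number-of-tests significance threshold, replication logic,
    and a signed -log10(p) Kendall-tau comparison of a GWAS locus with
    cis-eQTL association patterns. Includes a family-based synthetic
    cohort simulator (pedigrees, gene-dropping, imputation-like dosages,
    causal effects on the log10(cups + 1) scale) so the whole pipeline is
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
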