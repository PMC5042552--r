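Package: allogenomics
Title: Allogenomics Mismatch Scoring and Longitudinal Graft-Function Models for Transplant Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the allogenomics mismatch score (AMS), a burden-style
    tally of donor amino-acid alleles in transmembrane proteins that are
    absent from the recipient genome, from annotated donor/recipient VCF
    pairs. Provides quality filtering of genotype calls, selection of the
    scoreable site panel (missense sites in transmembrane genes),
    MDRD-based eGFR computation, cross-sectional and longitudinal
    mixed-model association analyses of AMS versus post-transplant kidney
    function, likelihood-ratio model comparison, and effect-impact
    reporting. Includes a synthetic-cohort generator (paired diploid
    genotypes with parent-child relatedness, rare-skewed allele
    frequencies, and longitudinal eGFR from a linear mixed model) so the
    whole pipeline can be validated end-to-end without real exomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
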