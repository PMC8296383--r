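Package: pgxsmoke
Title: Pharmacogenetic Analysis of Smoking-Cessation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-sectional pharmacogenetic analysis of smoking-related
    single nucleotide polymorphisms in two smoking-cessation cohorts.
    Loads a 31-SNP candidate panel (CYP2A6, NRXN1, DRD4, HTR2A, CHRNA3,
    CHRNA5), computes per-cohort genotype and allele frequencies, applies
    the published contingency-test decision rule (Pearson chi-square with
    optional Yates correction, Fisher and Freeman-Halton exact tests),
    classifies subjects into normal/intermediate/slow nicotine metabolizers
    from CYP2A6 star alleles or minor-allele counts, compares cohorts with
    nonparametric tests and age/gender matching, and reconstructs
    individual-level genotype data exactly from published genotype count
    tables for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
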