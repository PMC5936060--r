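Package: ishquant
Title: Densitometric Quantification and RFLP Genotyping of In Situ
    Hybridisation Experiments in Zebrafish Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unbiased quantification of chromogenic in situ hybridisation
    (ISH) signal in zebrafish embryo images by background-subtracted
    region-of-interest densitometry, in-silico PCR and restriction-digest
    (RFLP) genotype calling with IUPAC-degenerate recognition sites, and
    the accompanying statistical battery: group summaries with
    coefficients of variation, pooled and Welch t-tests, standard and
    Welch one-way ANOVA, Levene's test, Tukey HSD and Games-Howell
    post-hoc comparisons, contingency chi-squared tests, noncentral-t
    power and sample-size analysis, and delta-Ct relative quantification
    for single-embryo qRT-PCR. A synthetic-data generator produces
    embryo-like stained images with known genotype-conditional intensity,
    matched ROI files, allele sequence pairs and Ct tables, so the whole
    pipeline is testable end to end without any imaging hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    png,
    tiff,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse
Config/testthat/edition: 3
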