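Package: midflux
Title: Mass Isotopomer Distribution Analysis of Carbon Flux in Hepatocyte
    Steatosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of stable-isotope (U-13C-glucose) tracing experiments in
    cultured hepatocytes: normalization and natural-isotope-abundance
    correction of GC/MS mass isotopomer distributions (MIDs); estimation of
    lipogenic acetyl-CoA precursor enrichment and the fraction of new
    synthesis (FNS) of palmitate, stearate, and oleate by mass isotopomer
    distribution analysis (MIDA); desaturation and elongation
    precursor-to-product indices; the pyruvate carboxylase / pyruvate
    dehydrogenase (PC/PDH) ratio from glutamate TAB fragment isotopomers;
    summed 13C molar enrichment (SIGmn) of glycogen-derived glucose and RNA
    ribose; plate-reader assay arithmetic (medium glucose depletion, cell
    proliferation, Oil Red O fold change); and group statistics (Shapiro-Wilk,
    one-way ANOVA, Tukey HSD) with summary report tables. Includes a seeded
    synthetic-study generator so every estimator is validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
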