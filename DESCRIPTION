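Package: trdpheno
Title: Phenotyping Major Depression and Treatment Resistance from Primary Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines major depressive disorder (MDD) and treatment-resistant
    depression (TRD) from dated primary-care diagnostic and prescribing
    records in the style of UK general-practice extracts (Read v2 / CTV3
    clinical codes, drug issue tables). Prescriptions are chained into
    same-drug episodes, switches between antidepressants are detected under
    duration and gap rules, and per-patient phenotypes (case status, switch
    counts, adherence proxy, combination and augmentation flags, record
    density) are derived. A statistical layer provides prevalence, odds
    ratios, polygenic-score construction and logistic association with
    Nagelkerke R-squared, liability-scale conversions of heritability and
    variance explained under case-control ascertainment, effect-comparison
    z-tests and Bonferroni correction. A synthetic-cohort generator with a
    liability-threshold genetic model and configurable prescribing
    trajectories makes every stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
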