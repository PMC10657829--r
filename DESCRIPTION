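Package: herbmicrobeMR
Title: Prescription Mining and Two-Sample Mendelian Randomization for
    Herb-Microbiota Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One tested pipeline linking traditional-Chinese-medicine
    prescription mining to gut-microbiota causal inference: frequency,
    dosage and property/flavor/meridian statistics over prescription
    corpora; Bray-Curtis ordination with PERMANOVA and PLS-DA; Apriori
    association-rule mining; three-way therapeutic-target overlap with
    degree-based hub ranking and hypergeometric pathway
    over-representation; and a from-scratch two-sample Mendelian
    randomization engine (IVW, MR-Egger, weighted median, mode
    estimators) with Cochran's Q, MR-PRESSO, and Steiger directionality
    diagnostics. A synthetic-data module generates every input the
    pipeline consumes so the whole chain is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
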