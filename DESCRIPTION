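Package: lynchburden
Title: Rare-Variant Risk-Modifier Burden Analysis for Lynch Syndrome Carrier Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A family-based pipeline for identifying rare germline risk
    modifiers of cancer risk among Lynch syndrome mismatch-repair mutation
    carriers. Ingests per-subject variant calls (VCF) against a gene panel
    of estrogen-signaling and cancer-associated genes, filters variants on
    minor allele frequency (below 0.001, with a rescue rule for previously
    reported pathogenic polymorphisms), classifies them into the five
    clinical-genetics tiers using a deterministic rules engine built on
    amino-acid substitution conservativeness (physicochemical groups or
    Grantham distance), flags possible co-segregation with the familial
    mismatch-repair mutation, and tests whether carrying two or more
    risk-variants associates with a poor clinical phenotype (early
    endometrial cancer or multiple primary cancers) via exact
    contingency-table tests and Kaplan-Meier / log-rank survival
    comparison. Includes a seeded synthetic-cohort simulator with a
    controllable burden-to-phenotype odds ratio so every pipeline stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    methods,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
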