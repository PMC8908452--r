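Package: cinch
Title: Chromosomal Instability and Clonal Heterogeneity Scoring for
    Cytogenetic Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cytogenetic biomonitoring cohorts:
    parsing and canonical formatting of a working subset of ISCN-2020
    karyotype nomenclature, classification of numerical and structural
    chromosomal alterations with clonal (CCA) versus non-clonal (NCCA)
    calls, per-individual and per-group aberration frequency tables,
    chromosomal-instability (CIN) scoring from per-nucleus centromeric
    FISH signal counts, clonal-heterogeneity indices (Shannon diversity
    and true diversity), a gated two-group and omnibus statistics layer,
    and a fully synthetic cohort generator with known ground truth for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
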