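Package: truncalis
Title: Clonality and Saturation Analysis for Multi-Region Tumor Biopsies
Version: 0.1.0
Authors@R:
    person("Truncalis", "Developers", email = "truncalis@example.org",
           role = c("aut", "cre"))
Description: Analysis of somatic variants observed across spatially separated
    biopsies of a single tumor lesion. Classifies variants as truncal, branch
    or private from a binary presence matrix; performs combinatorial
    saturation analysis over biopsy subsets (unique variants, putative
    truncal variants and their positive predictive value) to determine the
    minimum number of biopsies required per gene panel; predicts truncal
    status in silico from a single biopsy by allele-frequency or
    cancer-cell-fraction thresholds with a grid search against the
    multi-biopsy ground truth; builds maximum-parsimony phylogenies with the
    germline as outgroup; evaluates truncal-mutation-directed therapy by
    progression-free-survival ratios; and generates synthetic multi-region
    cohorts with known clonal structure for validation.
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
    ape,
    phangorn,
    jsonlite
Config/testthat/edition: 3
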