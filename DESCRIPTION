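Package: SimCascade
Title: Ligand-Based Similarity Cascade and Target-Correlation Mining for
    Drug Repurposing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of a computational
    drug-repurposing workflow for cell-active compound collections:
    curation and deduplication of ChEMBL-style bioactivity tables,
    standardization of compound structures, a two-stage ligand similarity
    cascade (MACCS and ECFP4 Tanimoto filtering followed by Gaussian
    shape/pharmacophore overlay scored as TanimotoCombo), mining of
    biological targets whose potency profile correlates with cellular
    antiproliferative potency (tie-aware Spearman rho with Bonett-Wright
    confidence intervals), and integration of all evidence into a ranked,
    deterministic candidate report. Includes a fully seeded synthetic-data
    generator with planted structural analogs and planted driver-target
    correlations so that every stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
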