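Package: gwgenr
Title: Genetic and Epigenetic Network Identification with Systematic
    Multi-Target Drug Combination Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genome-wide genetic and epigenetic regulatory
    networks (protein-protein interactions plus TF/lncRNA/miRNA regulation
    of genes and non-coding RNAs) from expression data by constrained
    least-squares system identification with Akaike-information-criterion
    order detection, extracts core networks by principal network projection
    (singular value decomposition with an energy criterion), trains a
    feedforward drug-target interaction classifier, and selects minimal
    multi-target drug combinations under regulation-ability, sensitivity
    and toxicity specifications. Includes a seeded synthetic-data module
    that emulates the statistical structure of the expression and
    drug-target inputs so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
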