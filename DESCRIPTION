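Package: wonparafac
Title: Weighted Orthogonal Non-Negative PARAFAC for Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates mutation, copy-number and gene-expression matrices into a
    non-negative three-way data cube and decomposes it with a weighted,
    orthogonality-constrained non-negative PARAFAC (CP) model fitted by
    multiplicative alternating updates. Includes rank selection by AIC and
    factor redundancy, cell-set and gene-set enrichment of factors, per-compound
    elastic-net drug-response models on factor loadings with nested
    cross-validation, and projection of an independent cohort onto fixed gene
    and data-type factors with permuted-cube baselines. Seeded synthetic-data
    generators reproduce the statistical structure the method assumes, so all
    machinery is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
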