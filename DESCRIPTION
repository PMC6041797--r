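Package: pmfa
Title: Principal Metabolic Flux Mode Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variance-maximizing extraction of metabolic flux modes from
    fluxomic or reaction-level expression data. Principal metabolic flux
    mode analysis (PMFA) couples the variance objective of principal
    component analysis with a stoichiometric steady-state regularizer on
    the loadings, solved by a multi-start convex-concave procedure; a
    sparse variant (SPMFA) constrains the l1 norm of the loadings.
    Includes metabolic network input (SBML and a tabular dialect),
    gene-protein-reaction mapping of expression to reactions, elementary
    flux mode enumeration for small networks, a steady-state flux
    simulator with a relative noise model, the comparison methods PCA,
    sparse PCA, flux balance analysis and principal elementary mode
    analysis, and evaluation utilities (explained-variance fractions,
    elementary-mode retrieval curves, cross-validation).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
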