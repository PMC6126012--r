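Package: redoxsid
Title: System-Identification Analysis of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models (GEMs)
    oriented at redox-cofactor accounting in xylose-fermenting yeast. Provides
    flux balance analysis (FBA) and parsimonious FBA on models read from
    tabular reaction/metabolite tables or SBML (Level 3 FBC), phenotype phase
    plane computation with phase segmentation and line-of-optimality
    extraction, a system-identification workflow (designed linear condition
    sweeps, flux-matrix PCA, loading ranking, up/down/inactive response
    classification, forced-behavior probes), compartment-aware cofactor
    production/consumption ledgers with between-condition deltas and
    electron-balance bookkeeping, fitting of oxygen uptake and xylose
    reductase cofactor-preference ratio to measured ethanol yields,
    gene-protein-reaction (GPR) based reaction-expression scoring against
    transcriptome tables, and a self-contained toy-model generator with
    hand-verifiable optima for testing every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
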