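Package: fluxscreen
Title: Ensemble-Objective Flux Balance Analysis Knockdown Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constraint-based screening of genome-scale metabolic models
    under fractional gene knockdown. Every reaction of a model is maximized
    in turn by flux balance analysis under wild-type and knockdown flux
    bounds, where knockdown scales the bounds of gene-associated reactions
    toward zero; reactions whose maximal attainable flux drops by more than
    a threshold fraction are classified as compromised and summarized by
    metabolic subsystem. Includes an SBML (Level 3, fbc v2) reader/writer,
    a built-in linear-programming solver, generators for synthetic toy
    models with analytically known screen outcomes (linear chains, bypass
    branches, a hepatic valine/3-hydroxyisobutyrate pathway model, seeded
    random networks), and net metabolite appearance-rate calculations from
    conditioned versus unconditioned culture-medium concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
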