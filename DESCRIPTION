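Package: modrepo
Title: Module-Based Drug Repositioning from Case/Control Expression and GWAS Seed Networks
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects gene co-expression modules from case/control expression
    data with a weighted co-expression (TOM-based) workflow, selects
    disease-specific modules by a signed log-hypergeometric enrichment score
    against a GWAS-seeded regulatory network, and ranks candidate drugs by a
    Drug Effect Sum Score (DESS) that rewards reversal of module-level
    dysregulation. Includes a moderated (empirical-Bayes) differential
    expression filter, a synthetic data generator with planted ground truth,
    file-based TSV interfaces for every stage, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
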