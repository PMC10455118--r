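Package: cazyspec
Title: CAZyme Repertoire Comparison and Sugar-Specific Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of fungal plant-biomass-degrading
    carbohydrate-active enzymes (CAZymes). Ships a curated CAZy
    (sub-)family to enzyme-activity to plant-polysaccharide catalog,
    aggregates gene-level annotations into per-species family counts and
    per-substrate totals, computes a sugar specificity index (SSI, a
    tau-type expression-specificity statistic) over FPKM matrices measured
    on monosaccharide growth conditions, classifies sugar-specific genes
    and their inducing sugars, quantifies concordance between genomic
    degradative potential and ordinal growth profiles, and simulates
    expression data with planted sugar-specific genes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
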