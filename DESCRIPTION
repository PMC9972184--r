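Package: cladescope
Title: Interpretable Comparison and Visualization of Taxonomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Merges the outputs of up to three whole-genome-shotgun taxonomic
    profilers (optionally together with a ground-truth profile) onto a shared
    taxonomy tree and quantifies per-clade agreement. Reads the CAMI/Bioboxes
    profiling format and BIOM 1.0 JSON tables, resolves lineages against an
    NCBI-style taxonomy dump, classifies taxa as true-positive, false-positive
    or false-negative relative to a gold standard, computes per-rank L1 error,
    and renders publication-quality tree figures (SVG, optional PNG) in which
    disc size encodes relative abundance and color encodes either per-source
    agreement or error-proportional contrast. Includes a synthetic-data
    generator producing miniature taxonomy dumps and perturbed profile sets
    with a known record of injected and dropped taxa, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    biomformat,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
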