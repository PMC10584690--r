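Package: chromfiber
Title: Single-Molecule Chromatin Fiber Accessibility Decoding and
    Nucleosome Array Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-molecule chromatin footprinting analysis:
    decoding per-molecule DNA accessibility from adenine methylation calls
    with a two-state chain hidden Markov model, calling nucleosome
    footprints and per-fiber nucleosome density, characterizing fiber
    architecture by autocorrelation and Leiden clustering, Monte-Carlo
    simulation of nucleosome arrays remodeled by clamping ("ruler") versus
    length-sensing processes, Student's-t mixture thresholding of kinetic
    residuals, and enrichment statistics (Fisher's exact tests with Storey
    q-values, log-odds density enrichment, PCA, weighted interval
    scheduling). Includes a seeded synthetic-data generator so every stage
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    uwot,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
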