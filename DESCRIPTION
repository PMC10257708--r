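Package: phenoRG
Title: Phenomenological Renormalization-Group Analysis of Large-Scale
    Binary Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scale-invariance diagnostics for binarized multivariate
    recordings of whole-brain activity. Implements the distance-resolved
    correlation function, the phenomenological renormalization group
    (PRG) based on maximally correlated pairing and its
    connectivity-based variant, least-squares power-law fitting with an
    exponential alternative and explained-variance model comparison,
    exponential-distance-rule (EDR) connectome fitting and generation,
    and a pairwise spin model on a weighted connectome sampled with the
    Metropolis algorithm, including exact enumeration for small systems,
    inverse-temperature scans and critical-point location. A
    synthetic-data module generates geometries, EDR connectivities and
    binary rasters with controlled correlation structure so every stage
    can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
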