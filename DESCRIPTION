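Package: clsmverse
Title: Multiverse Analysis of Connectome-Based Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectome-based lesion-symptom mapping (CLSM) and for
    assessing how its many processing choices change the result. Computes
    direct and indirect tract-based disconnection metrics (lesion percentage,
    disconnection percentage, tract volume, streamline count, mean diffusion
    scalars), parcel-based structural connectomes at whole-brain and
    region-of-interest scales, and six weighted graph-theory summaries via a
    normalize-invert-shortest-path chain. A statistical engine runs the
    multiverse of brain-behaviour analyses: covariate-adjusted add-one
    regressions with delta R-squared grids, rank-correlation similarity of
    connectomes, and sparse canonical correlation with cross-validation. A
    synthetic stroke-cohort generator with planted ground truth makes every
    stage testable without imaging downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
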