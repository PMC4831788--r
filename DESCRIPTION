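Package: sfCCA
Title: Structure-Function Connectome Coupling via Sparse CCA Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds structural connectomes from streamline-weighted
    microstructural indices (FA, MD, NODDI-derived ICVF, ODI, ISO, kappa) and
    functional connectomes from precision matrices of regional time series or
    band-limited Hilbert envelopes, then identifies the structural connections
    that predict functional connectivity. The core method is rank-1 sparse
    canonical correlation analysis with randomised-Lasso penalty weights,
    embedded in a bootstrap-over-subjects stability selection, with an exact
    binomial-tail rule that accepts or rejects each connection relative to its
    chance selection probability. Includes a synthetic-data module with known
    ground truth for calibration and recovery testing, readers and writers for
    labeled connectivity matrices, probability-map export, hemispheric
    fingerprints of selected edges, and pairwise index correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'connectome-io.R'
    'connectome-construction.R'
    'synthetic.R'
    'scca.R'
    'stability.R'
    'reporting.R'
    'sfCCA-package.R'
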