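Package: taylorconn
Title: Predicting Haemodynamic Connectivity from Electrophysiological
    Networks via Multivariate Taylor Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to model a haemodynamic (fMRI-like) functional
    connectivity matrix as a multivariate Taylor expansion of a stack of
    electrophysiological (MEG-like) connectivity matrices computed per
    frequency band and coupling mode.  Includes the phase lag index,
    leakage-corrected amplitude envelope correlation and Pearson
    connectivity metrics with band-pass filtering and analytic-signal
    extraction; Gaussian distance-weighted ROI aggregation; construction
    and least-squares estimation of nested Taylor models (linear,
    quadratic and cross-frequency terms); spectrum-preserving
    pseudo-matrix null models; permutation tests for variance explained,
    complexity gradients and model increments; and a synthetic-data
    generator for planted-coefficient targets and coupled oscillatory
    time series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
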