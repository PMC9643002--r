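Package: hippotrack
Title: Hippocampal Long-Axis Tractography, Streamline Weighting and
    Endpoint Density Mapping
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for quantitative fibre tracking of the
    hippocampus. Implements the five-tissue-type (5TT) model for
    anatomically constrained probabilistic tractography, a modified-5TT
    amendment that removes the grey/white interface immediately inferior
    to the hippocampus so that streamlines can permeate it, probabilistic
    streamline tracking on spherical-harmonic fibre-orientation
    distribution (FOD) fields, SIFT2-style per-streamline weight fitting
    against FOD-derived fibre density, weight-sum connectivity tables
    between cortical parcels and the whole/head/body/tail hippocampus,
    super-resolution track-density and endpoint-density mapping, and
    paired-comparison statistics with a four-way classifier of long-axis
    connectivity patterns. Includes a synthetic phantom generator with
    known ground truth so the full pipeline is testable end to end, and
    readers/writers for MRtrix .tck tractograms, SIFT2-convention weight
    files and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
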