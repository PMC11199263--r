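Package: microstates
Title: EEG Microstate Segmentation, Backfitting and Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis of continuous
    multichannel recordings: global field power (GFP) peak extraction,
    polarity-invariant modified k-means clustering at the individual and
    group level with resampling and a meta-criterion for selecting the
    number of states, winner-take-all backfitting with temporal smoothing
    and small-segment rejection, per-state temporal properties (global
    explained variance, duration, coverage, occurrence) and first-order
    Markov transition statistics. Includes a reliability battery
    (duration-truncation stability, even/odd split-half internal
    consistency with Spearman-Brown correction, boxplot outlier screening,
    slice-wise Dice overlap of binary volumes) and a synthetic-EEG cohort
    generator with planted microstate structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
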