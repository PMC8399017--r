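Package: pdgait
Title: Quantifying Parkinsonian Gait from Markerless Pose Key-Point Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, clinically interpretable quantification of
    gait impairment in Parkinson's disease from markerless pose estimation
    output. Reads BODY_25 key-point time series, constructs seven normalised
    gait signals, estimates step frequency with a conjugate Gamma-Poisson
    model over detected gait-cycle events, derives six interpretable features
    (speed, arm swing velocity and amplitude, postural control, and movement
    roughness), and classifies MDS-UPDRS gait item severity (0-3) with an
    ordinal decomposition into three binary random forests. Per-prediction
    explanation artefacts include eccentricity tables, exact Shapley value
    decompositions and impurity importances. A synthetic walking-skeleton
    generator with controllable cadence, arm swing, stride-width variability
    and noise supports end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
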