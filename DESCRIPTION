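Package: tntmvpa
Title: Multivariate EEG Decoding and Cluster Statistics for Retrieval
    Suppression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Time-resolved multivariate pattern analysis of epoched EEG from
    Think/No-Think retrieval-suppression experiments: condition- and
    item-level decoding with sub-ERP averaging and cross-validated linear
    support vector machines, empirical chance estimation from pre-stimulus
    baselines, Morlet time-frequency decomposition with decibel baselining,
    channel-searchlight decoding over triangulation neighborhoods,
    nonparametric cluster-based permutation inference (time, time-frequency
    and channel domains), representational similarity analysis against
    subjective dissimilarity ratings, and behavioral statistics
    (repeated-measures ANOVA with Greenhouse-Geisser correction, paired
    contrasts with Cohen's dz, brain-behavior correlations). Includes a
    synthetic Think/No-Think EEG generator with known ground truth so every
    stage of the pipeline can be exercised and calibrated without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
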