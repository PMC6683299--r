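Package: gazetrans
Title: Scanpath Transition Analysis for Eye-Tracking Studies of Medical Images
Version: 0.1.0
Authors@R: person("Gaze", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing visual scanpaths between groups of viewers.
    Fixation-level eye-tracking data are discretised into areas of interest
    (AOIs), either semantic regions such as the twelve leads of an ECG or a
    data-driven uniform grid whose cell size is derived from DBSCAN density
    clustering of the fixation points. AOI label sequences are summarised as
    directed transition matrices and Markov chains, group differences are
    quantified with the Hellinger distance between pooled transition
    distributions, and inference uses a participant-shuffling permutation
    test. Conventional repeated-measures statistics (McNemar per stimulus,
    paired Wilcoxon signed-rank on fixation metrics, Bonferroni control) and
    a fully parameterised synthetic-study simulator for calibration and
    power analysis are included, together with a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
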