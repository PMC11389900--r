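Package: trialvar
Title: Cross-Trial Variability Analysis of Oscillatory EEG Power
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying cross-trial variability of single-trial
    oscillatory EEG power in working-memory experiments. Implements a
    delayed match-to-sample task schedule generator; a synthetic-EEG
    generator with parameterized 1/f background, phase-locked evoked
    components and non-phase-locked beta-band bursts whose cross-trial
    amplitude variance, behavioral accuracy and previous-trial coupling
    are all planted and recoverable; trial-level cleaning (amplitude,
    improbability and kurtosis rejection, reaction-time filtering,
    phase-locked subtraction); single-trial Morlet time-frequency
    decomposition with decibel baseline normalization and
    signal-to-noise estimation; the cross-trial relative-variance
    statistic with band, window and channel-cluster aggregation,
    within-trial variability and median-split diagnostics; and the
    associated inference procedures (load-slope tests, mixed models,
    permutation and cluster-based permutation tests, subsampled
    contrasts, and lagged single-trial models relating post-response
    power to next-trial accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
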