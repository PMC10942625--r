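Package: thetalink
Title: Theta-Band Representational Similarity and Connectivity Analysis of
    Narrative-Insight EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for EEG studies of
    insight-driven memory reconfiguration. Provides a synthetic session
    generator emulating a narrative-insight design (10 stories x 3 events x
    2 phases, two stimulation groups, two insight modes), a minimal
    preprocessing chain (epoching, average reference, demean/detrend, DFT
    notch, anti-alias downsampling, amplitude rejection), sliding
    Hanning-window time-frequency decomposition with absolute baseline
    correction, time-by-time theta-band representational similarity maps
    with Fisher-z averaging, nonparametric cluster-based permutation t-tests
    over electrode-by-time spaces with an exhaustive small-sample oracle,
    sliding-window imaginary coherence at the mean theta frequency, and
    follow-up statistics (paired and Welch t tests, 2x2 mixed interaction
    with generalized eta squared, correlation and independent-correlation
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
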