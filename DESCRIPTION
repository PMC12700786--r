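Package: thalcortex
Title: Thalamo-Cortical Phase-Synchronisation Analysis for Combined DBS
    LFP and EEG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing oscillatory functional connectivity
    between thalamic local field potentials recorded by a sensing-enabled
    deep brain stimulation pulse generator and simultaneous high-density
    scalp EEG. Provides readers and writers for Percept-style BrainSense
    streaming JSON and BrainVision file triplets, artifact-based clock
    synchronisation, tic-event selection and epoching rules, Morlet
    wavelet time-frequency decomposition, the phase synchronisation index
    (PSI) with trial-shuffled surrogates and sliding-window variants, a
    Monte-Carlo permutation inference engine (paired t-tests, multi-way
    ANOVA with post-hoc comparisons, Benjamini-Hochberg FDR,
    cluster-based multiple-comparison correction, exact and permutation
    Spearman correlations, linear trend regression), and a synthetic-data
    generator with von Mises phase coupling whose ground truth supports
    parameter-recovery testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
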