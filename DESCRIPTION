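Package: nmjquant
Title: Synthetic Electrophysiology and Postsynaptic Morphometry of the
    Neuromuscular Junction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses intracellular recordings (miniature and
    evoked endplate potentials, 20 Hz stimulus trains) and en-face fluorescence
    micrographs of the mouse neuromuscular junction, reproducing a quantal and
    morphometric characterisation of synaptic decline in the SOD1-G93A model of
    ALS. Provides ground-truth-bearing generators for voltage traces and
    acetylcholine-receptor "pretzel" images; event detection with membrane
    potential correction and Martin quantal-content estimation; vesicle-pool
    rundown profiling; NMJ-morph style postsynaptic variables; box-counting
    fractal perimeter dimension; intensity-histogram bimodality statistics;
    disruption classification; and the study-level statistical comparisons
    (two-way ANOVA with Bonferroni post-tests, Ansari-Bradley and Mann-Whitney
    tests, variance-ratio F tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    ggplot2,
    readr
Config/testthat/edition: 3
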