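Package: soundnav
Title: Simulation and Analysis of Navigation Through an Auditory Density Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying "navigation" along a non-spatial auditory
    feature: the spectral density of tone stacks (the number of concurrent
    random-frequency pure tones). The package synthesizes tone-stack stimuli
    on a logarithmically spaced density scale, generates fully resolved runs
    of a four-condition memory-by-adjustment design with yoked acoustic and
    digit controls, simulates psychometric and navigating observers
    (including a two-down/one-up adaptive staircase), scores behavior
    (navigation distance, dislocation-tolerant parity accuracy, rating
    correlations), and analyzes synthetic multi-subject BOLD data with a
    first/second-level GLM (canonical HRF, centered orthogonalized parametric
    modulators, sign-flip permutation FWE control) and an across-participant
    crossnobis searchlight with Ledoit-Wolf variance-retaining noise
    normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
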