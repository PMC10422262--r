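Package: mmgfs
Title: Mechanomyography Movement Recognition with Swarm-Based Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pattern recognition of limb movements from multichannel
    mechanomyography (MMG) recordings. Provides band-pass filtering and
    short-time-energy segmentation of raw recordings, extraction of four
    feature families (time domain, frequency domain, wavelet-packet node
    energy, and nonlinear dynamics: approximate/sample/fuzzy entropy and
    Lempel-Ziv complexity), and wrapper feature selection driven by the
    chameleon swarm algorithm (CSA) and the grasshopper optimization
    algorithm (GOA) with transfer-function binarization, scored by
    cross-validated SVM-RBF classification accuracy. Includes a seeded
    generator of MMG-like synthetic datasets and experiment drivers for
    feature-set, channel-combination and threshold-sweep comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
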