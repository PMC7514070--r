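Package: dendrosim
Title: Simulation of Signal Contamination in Dendro-Provenancing Reference Chronologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing the contamination risk of tree-ring reference
    chronologies used in dendro-provenancing. Generates covariance-preserving
    pseudo site signals from autoregressive residual site chronologies, samples
    pseudo historical series and pseudo object chronologies from them, grows
    pseudo reference chronologies with an iterative one-nearest-neighbour
    best-match constructor under t-value thresholds, and quantifies signal
    stability, misclassification and off-site/off-contrast contamination over
    many simulation repetitions. Includes readers and writers for decadal
    Tucson (RWL) ring-width files and a synthetic fixture generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
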