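Package: norcage
Title: Automated Homecage Novel-Object-Recognition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous homecage novel-object-recognition
    (NOR) experiments recorded at low frame rate with overhead pose tracking.
    Classifies per-frame object exploration from body-part keypoints (a
    transparent geometric rule and a random-forest classifier), computes
    exploration time courses, discrimination indices and the paired
    (test minus sample) discrimination index, latency and peak-exploration
    statistics, first-approach proportions, nest-position and corridor-exit
    bias analyses, and an annotator-agreement surrogate model that quantifies
    how robust the discrimination index is to disagreement between annotators.
    Includes a synthetic session generator (a Markov-modulated state process
    over nest, corridor, roaming and per-side exploration states) so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    randomForest,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
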