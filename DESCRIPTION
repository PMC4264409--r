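Package: redint
Title: Feature-Based Redintegration Memory Model and Self-Paced Reading Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a feature-based cue-redintegration model of memory
    retrieval during sentence comprehension: slot-aligned feature-vector
    similarity, Luce-ratio sampling probabilities, distinctiveness and
    competitor-load sweeps, and an encoding-interference (feature
    overwriting) extension that links noun-phrase elaboration to retrieval
    at relative-clause verbs. Also provides a synthetic self-paced-reading
    data generator with Latin-square factorial designs, word-length and
    practice effects, and crossed random effects, plus the standard
    reading-time analysis pipeline: trimming, log-transformation,
    residualization against word length and list position, sum coding, and
    hierarchical Bayesian regression reporting posterior sign probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
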