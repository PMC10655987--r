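Package: betagate
Title: Oscillating Prediction-Error Precisions for Online Syllable Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical predictive-coding model of online syllable
    recognition in which the precision (inverse variance) of bottom-up
    prediction errors oscillates at a configurable rate, rhythmically
    alternating bottom-up and top-down dominance during inference. The
    generative model couples a canonical theta neuron tracking the speech
    amplitude envelope, an eight-unit gamma-rate sequence (stable
    heteroclinic channel) indexing position within a syllable's
    spectrotemporal template, evidence-accumulating syllable units, and a
    spectral relaxation stage. Includes a seeded synthetic syllable-corpus
    generator, precision-weighted gradient-flow inversion, five evaluation
    metrics (overlap, entropy-weighted overlap, longest common subsequence,
    sensory-integration efficacy, and a categorical log-likelihood/BIC),
    and a frequency-sweep experiment harness with bootstrap and paired
    nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
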