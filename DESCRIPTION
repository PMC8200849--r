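Package: pdvoice
Title: Dopaminergic Motor-State Classification from Parkinsonian Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to differentiate the ON and OFF dopaminergic motor states
    of people with Parkinson's disease from structured speech recordings.
    Implements a phone-attribute codebook (PAC) instance-based classifier
    built on 1-bit quantized phonological posterior features with Jaccard
    fallback matching, a convolutional-recurrent network (CRNN) trained on
    normalized spectrograms of 10-s speech segments, per-patient selection of
    informative speech protocols (p-CRNN), feature-level statistics (paired
    t-tests, attribute correlations, 2-D embeddings), and a
    leave-one-patient-out evaluation harness. A fully synthetic patient
    cohort generator (audio, posterior streams, manifest, clinical-style
    score table) makes the whole pipeline exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
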