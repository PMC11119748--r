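Package: pathospeech
Title: Automatic Assessment and Telemonitoring of Speech Intelligibility and
    Disorder Severity
Version: 0.1.0
Authors@R:
    person("Pathospeech", "Maintainers", email = "maintainers@pathospeech.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for the automatic prediction of speech
    intelligibility and speech-disorder severity from passage-reading
    recordings of patients treated for head and neck cancer. Maps mono WAV
    recordings to fixed 512-dimensional speaker embeddings through a
    time-delay neural network with statistics pooling, regresses the two
    perceptual scores (0-10 clinical scale) with a shallow multi-task
    network trained by Adam, and evaluates predictions with Spearman's rank
    correlation, RMSE and the intraclass correlation coefficient (two-way
    mixed effects, absolute agreement). Includes pitch-preserving tempo
    augmentation (WSOLA), energy-based passage segmentation into eight
    clinically standard segments, a synthetic-cohort generator with known
    ground truth for validation without clinical data, and a longitudinal
    patient score registry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
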