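Package: bowelsound
Title: Bowel-Sound Detection and Defecation Prediction from Abdominal
    Auscultation Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing abdominal auscultation audio with the goal of
    predicting imminent defecation from bowel-sound activity. Implements an
    iterative kurtosis-based detector that separates sparse bowel-sound bursts
    from the quasi-Gaussian physiological background, a constant-acceleration
    Kalman filter for denoising the extracted burst channel, time-domain,
    frequency-domain and Haar-wavelet feature extraction, a from-scratch
    single-hidden-layer backpropagation classifier with momentum, and a
    repeated stratified train/test evaluation protocol. A seeded synthetic
    bowel-sound generator with ground-truth burst annotations makes the whole
    pipeline testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
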