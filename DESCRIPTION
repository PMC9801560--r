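Package: pbdtss
Title: Transcription Start Site Prediction from DNA Breathing Profiles
    and String Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes equilibrium base-pair opening and denaturation-bubble
    probabilities of DNA sequences under the Peyrard-Bishop-Dauxois (PBD)
    mesoscopic model, using an iterative one-dimensional transfer-integral
    quadrature over the configurational partition function. The resulting
    per-base probability profiles are combined with weighted degree string
    kernels in a hybrid-kernel support vector machine to predict
    transcription start sites (TSSs), with imbalance-aware evaluation
    (sensitivity, specificity, G-mean, auROC), random undersampling, and a
    seeded synthetic benchmark generator emulating TSS window datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    kernlab,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
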