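Package: wyldomkit
Title: Profile-HMM Survey of WYL Domain Transcription Factor Architectures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to survey WYL domain-containing bacterial transcription
    factors by profile hidden Markov model analysis. Implements a
    self-contained Plan7-style profile-HMM engine (local multi-hit Viterbi and
    Forward scoring in bits, domain envelope extraction, Gumbel E-value
    calibration, threshold-driven search and scan), the iterative seed
    maturation protocol used to define the WYL, WCX and winged-HTH domain
    models, clan-level domain architecture classification, taxonomic
    distribution summaries, and a fully deterministic synthetic
    reference-proteome generator with planted domain architectures and ground
    truth so that every pipeline stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
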