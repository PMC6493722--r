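Package: screamr
Title: Acoustic and Statistical Analysis of Primate Agonistic Screams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for the analysis of agonistic scream
    vocalisations in group-living primates: a synthetic scream and study
    simulator with known ground-truth effects, WAV and annotation
    (CSV/Praat TextGrid) input-output, amplitude-gated segmentation of
    screams into bouts and agonistic events, spectro-temporal feature
    extraction (duration, peak frequency, frequency quartiles, spectral
    entropy, frequency modulation, and non-linear phenomena such as
    frequency jumps, subharmonics, biphonation and deterministic chaos),
    permuted discriminant function analysis with jack-knifed
    cross-validation for caller identity and context, and mixed-effects
    inference on social role, conflict severity and third-party support
    with Benjamini-Hochberg false-discovery-rate control and Cohen's
    kappa inter-observer reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
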