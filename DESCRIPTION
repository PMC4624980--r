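Package: cacor
Title: Cortico-Acoustic Correlation Analysis of EEG Responses to Continuous Sound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the note-onset structure (audio power slope) of
    continuous sound from multichannel EEG using temporally-embedded
    shrinkage-ridge regression, and quantifies the resulting cortico-acoustic
    correlation (CACor) with autocorrelation-aware significance tests
    (phase-randomised surrogates and effective-degrees-of-freedom correction).
    Includes extraction of nine acoustic and musical descriptors from audio
    waveforms, transformation of regression filters into interpretable
    spatio-temporal patterns with dipole-based MUSIC decomposition on a
    spherical head model, activity analysis of continuous behavioural rating
    sets, and a forward-model synthetic-data generator for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
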