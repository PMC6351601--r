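Package: neurovoc
Title: Speech Reconstruction from Auditory Cortex Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for reconstructing intelligible speech from multichannel
    auditory-cortex recordings. Implements a cochlear (auditory) spectrogram
    model with iterative waveform inversion, extraction of low-frequency and
    high-gamma-envelope neural features with silence-baseline normalization,
    regularized linear and deep-network decoders driven by a combined
    mean-squared-error and correlation loss, a vocoder parameter contract
    (spectral envelope, fundamental frequency, voicing and aperiodicity) with
    an autoencoder bottleneck compression stage, extended short-time objective
    intelligibility (ESTOI) scoring, and a forward encoding simulator that
    generates spectrotemporal-receptive-field driven synthetic neural
    responses for end-to-end evaluation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
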