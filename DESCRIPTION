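Package: eegbss
Title: Blind Source Separation Based Artifact Reduction for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic reduction of ocular and muscular artifacts in
    multichannel electroencephalogram (EEG) recordings by determined blind
    source separation. Implements time-domain extended infomax independent
    component analysis (ICA), frequency-domain natural-gradient independent
    vector analysis (IVA), and independent low-rank matrix analysis (ILRMA)
    with majorization-minimization source-model updates and iterative-
    projection demixing updates, together with short-time Fourier analysis/
    synthesis, independent-component feature extraction (scalp topography,
    median Welch power spectral density, autocorrelation), pluggable
    component labelling, label-driven signal reconstruction, a ground-truthed
    synthetic EEG generator, and evaluation utilities (permutation-aligned
    correlation, Amari index, canonical-correlation SSVEP frequency
    identification).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
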