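Package: vhitwca
Title: Wavelet Coherence Analysis of Video Head Impulse Test Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Time-frequency analysis of paired head and eye angular-velocity
    recordings from the video head impulse test (vHIT). Computes the analytic
    Morlet continuous wavelet transform, smoothed cross-spectra and the
    magnitude-squared wavelet coherence (MSWC) between head and eye velocity,
    and derives the coherent-frequency statistic (the highest frequency at
    which MSWC stays above 0.9 over the whole exam). Includes a calibrated
    synthetic vHIT cohort generator, vestibulo-ocular reflex (VOR) gain and
    saccade feature extraction, minority-class augmentation of time series
    (over-sampling, extensive data extraction, interpolation), rendering of
    coherence maps into cropped and tiled raster images, and outcome
    classification via convolutional feature extraction with a linear support
    vector machine under repeated stratified k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    e1071,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'vhitwca-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'wavelet.R'
    'simulate.R'
    'features.R'
    'augment.R'
    'imaging.R'
    'classify.R'
    'io.R'
    'utils.R'
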