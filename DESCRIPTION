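Package: sersnet
Title: Lightweight 1D Convolutional Networks for SERS Identification of
    PAH Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and classification pipeline for surface-enhanced
    Raman spectroscopy (SERS) of polycyclic aromatic hydrocarbon (PAH)
    mixtures on produce surfaces. Provides a Raman spectrum data model
    with resampling, normalization, peak-intensity extraction and
    relative-standard-deviation statistics; a synthetic SERS spectrum
    generator with Lorentzian bands, Langmuir-type competitive-adsorption
    amplitudes, fluorescence baseline and replicate variability; three
    lightweight one-dimensional convolutional network architectures
    (fire modules, depthwise-separable convolutions, grouped convolutions
    with channel shuffle) trained with Adam on softmax cross-entropy; and
    stratified dataset splitting with multiclass accuracy, precision,
    recall and F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
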