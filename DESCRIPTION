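Package: wvdimage
Title: Wigner-Ville Image Encodings for Classifying Molecular-Biology Feature Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 1D real-valued feature vectors (peptide embeddings, aptamer
    descriptors, DNA-barcode features) into 3-channel 2D images via a smoothed
    pseudo Wigner-Ville distribution with randomly sampled increasing Kaiser
    windows, alongside reshape, continuous-wavelet and discrete-wavelet baseline
    encoders. Trains ensembles of small convolutional image classifiers on the
    encodings (one random feature permutation and one window draw per member),
    averages their class scores, and fuses ensembles with a grid-search-optimized
    radial-kernel support vector machine via z-normalized weighted mean rules.
    Includes a synthetic-data generator with controllable spectral and mean-shift
    class structure, evaluation metrics (AUC, accuracy, stratified k-fold), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    png,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
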