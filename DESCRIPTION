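Package: promodiff
Title: Promoter Design by Denoising Diffusion with Transformer Strength Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing bacterial promoter sequences with a denoising
    diffusion probabilistic model (DDPM) and screening them with a
    transformer-encoder strength regressor. Implements one-hot and
    three-stream token encodings of fixed-length promoter sequences,
    log10/min-max strength normalization, forward Gaussian noising and
    ancestral sampling over one-hot sequence matrices, an L1-trained
    convolutional noise predictor, scaled dot-product self-attention with a
    combined mean-squared-error and Pearson-correlation loss, a convolutional
    baseline regressor, generation-quality metrics (sliding-window k-mer
    spectra and cross-set k-mer correlation, positional k-mer profiles,
    sequence-logo information content), in-silico saturation mutagenesis with
    a two-class mutation taxonomy, a seeded motif-structured synthetic
    promoter generator with a known strength law, and an end-to-end
    generate-screen-evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Biostrings,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
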