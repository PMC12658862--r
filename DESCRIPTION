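Package: xlratio
Title: Fragment Intensity Ratio Prediction and Rescoring for Cross-Linking Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for exploiting the log2 fragment ion intensity ratio between
    the two peptides of a cross-linked pair. Computes measured intensity ratios
    from MGF peak lists and cross-linked spectrum match (CSM) tables, fits a
    shared-encoder convolutional network with a cross-attention layer that
    predicts the ratio from the peptide pair sequences, and rescores CSMs by
    combining the prediction error (DiffIRScore) with a decoupled dot product
    spectral similarity (DDPScore) under target-decoy false discovery rate
    control. Includes a synthetic data generator with an additive per-residue
    ground truth and a sampling Shapley attribution workflow for per-residue
    interpretation of the fitted model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
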