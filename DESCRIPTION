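Package: tensorfe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised selection of differentially expressed features from
    omics tensors. A feature x replicate x condition tensor is decomposed by
    higher-order singular value decomposition (Tucker/HOSVD); sample-mode
    singular vectors are scored for replicate constancy and ordinal-condition
    monotonicity, the matching feature-mode singular vector is found through
    the core tensor, and features are selected with chi-squared P-values under
    a Gaussian null whose standard deviation is optimized so that the P-value
    histogram is flat outside the signal tail, followed by Benjamini-Hochberg
    correction. A shared-sample Gram-tensor variant integrates several omics
    layers measured on the same samples without materializing the full
    feature-space tensor. Includes a synthetic-data generator with planted
    ground truth, readers for TSV/CSV/MatrixMarket matrices with a sample
    design sheet, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
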