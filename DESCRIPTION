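Package: rosc
Title: Robust Overcomplete Sparse Coding with Low-Rank Prefiltering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage sparse coding of sensory stimuli: robust principal
    component analysis (inexact augmented Lagrangian) decomposes a patch
    matrix into a low-rank "typical" part and a sparse "atypical" part, and
    the atypical part is then encoded by overcomplete dictionary learning
    with greedy (Subspace Pursuit) and stochastic (Cross-Entropy over
    Bernoulli supports, and the combined Subspace Cross-Entropy) sparse
    solvers. Includes synthetic generators for planted low-rank plus sparse
    matrices, 1/f images, dictionary-sparse signals and Gabor patches, plus
    a receptive-field analysis toolkit: reverse correlation, Gabor fitting
    with shape parameters, reconstruction SNR and radial amplitude spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    data.table,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
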