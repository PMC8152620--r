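Package: nmrdp4
Title: Automated 1D NMR Processing and DP4 Stereochemistry Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic processing of raw 1D 1H and 13C NMR data
    (Fourier transform, hybrid entropy/regression phase correction, baseline
    correction, derivative peak picking, generalized-Lorentzian deconvolution
    with Bayesian-information-criterion noise pruning, solvent removal and
    referencing, integer-integral normalization), followed by automatic
    assignment of DFT-calculated chemical shifts to experimental peaks by
    Hungarian linear-sum matching with three-stage linear scaling, amplitude
    weighting and multiple-assignment penalties, and Bayesian DP4 ranking of
    candidate stereoisomers. Includes a synthetic-fixture generator producing
    ground-truth raw NMR data and calculated-shift tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
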