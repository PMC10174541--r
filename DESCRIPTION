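Package: sterilopt
Title: Neural-Network Surrogates and Multi-Objective Optimization for In
    Vitro Seed Sterilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reanalysis toolkit for disinfectant x immersion-time seed
    sterilization experiments in plant tissue culture. Expands published
    treatment means and standard errors into replicate-level observations,
    fits three surrogate regressors (a Levenberg-Marquardt trained
    multilayer perceptron, a radial basis function network with k-means
    centers, and a generalized regression neural network) to contamination
    rate and seed germination percentage, scores them by R2/RMSE/MBE,
    ranks input importance by variable-removal error ratios, and couples
    the best surrogate to an NSGA-II multi-objective search with
    ideal-point selection to recommend disinfectant concentrations and
    immersion times that jointly minimize contamination and maximize
    germination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
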