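Package: camsched
Title: CAM-Guided Redesign of Drug Schedules in Simulated 3D Cancer Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A closed-loop in-silico pipeline for studying drug-administration
    schedules in 3D cancer-cell cultures. A hybrid discrete/continuous lattice
    simulator generates multivariate time series (living and dead cells, mean
    glucose, mean oxygen, mean matrix Young's modulus) for cultures treated
    with doxorubicin and the LOX inhibitor BAPN. A multi-scale 1D convolutional
    network (inception-style, trained as a five-fit ensemble) classifies
    treatment outcome into complete response, partial response, stable and
    progressive neoplastic growth. Class activation maps localize the temporal
    features that define each class, and those features drive the comparison
    of alternative administration schedules via outcome-prevalence tables.
    Includes a controlled sine/square/sawtooth benchmark for validating that
    class activation maps localize class-bearing signal regions, and ARFF/CSV
    serialization of labeled multivariate series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
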