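Package: veinfrail
Title: Spatial Survival Modelling of Embolism Propagation in Leaf Vein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the spatio-temporal spread of xylem embolism
    through leaf venation networks observed with the optical vulnerability
    technique. Extracts a vein-segment graph with per-segment thickness from a
    binarized vein mask, maps per-frame embolized pixels (tagged with water
    potential) onto segments as right-censored time-to-event data, and fits
    Bayesian proportional-odds Weibull survival models with per-segment
    frailties under independent Gaussian or intrinsic conditionally
    autoregressive (ICAR) priors, optionally with a vein-thickness covariate.
    Includes a Kaplan-Meier baseline, credible-band-area comparison, deviance
    information criterion, temporal-split concordance index, vulnerability-curve
    conversion with P50 extraction, venation features (connectivity, vein
    density, areoles per area), between-species correlation summaries, and a
    synthetic-data generator for vein networks, frailty fields and embolism
    events.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    igraph,
    survival,
    coda,
    jsonlite,
    png,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
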