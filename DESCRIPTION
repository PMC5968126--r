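Package: fibrofocal
Title: Atrial Fibrosis, Body-Surface P-Wave Integral Maps, and Ectopic Focus Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis toolkit for studying how atrial
    fibrosis degrades non-invasive localization of focal atrial tachycardia
    sources. Implements the Courtemanche-Ramirez-Nattel human atrial myocyte
    model with regional conductance heterogeneity and the MacCannell active
    fibroblast model; a voxel-grid monodomain reaction-diffusion solver with
    operator splitting for mixed myocyte/fibroblast tissue slabs; a stochastic
    patchy-fibrosis generator with Utah staging; a synthetic two-chamber atrial
    surface and torso electrode atlas with fast-marching (eikonal) activation
    mapping; a dipole-sum forward model producing noisy, filtered body-surface
    potential integral maps (BSPiM); and a machine-learning pipeline (electrode
    reduction, Ward clustering, graph-based cluster validation, chi-square
    feature selection, RBF-SVM classification with stratified cross-validation)
    that maps BSPiMs to atrial regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    signal,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
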