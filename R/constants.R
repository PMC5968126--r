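#' Regional atrial electrophysiology parameters
#'
#' Cellular and tissue heterogeneity across 11 atrial regions: multiplicative
#' factors on the maximum conductances of three currents of the
#' Courtemanche-Ramirez-Nattel myocyte model (transient outward `g_to`,
#' L-type calcium `g_CaL`, rapid delayed rectifier `g_Kr`), the longitudinal
#' tissue conductivity `sigma_l` (S/cm), the transverse-to-longitudinal
#' anisotropy ratio, and the longitudinal conduction velocity `cv_l` (cm/s).
#'
#' Regions: right atrium (RA), pectinate muscles (PM), crista terminalis /
#' Bachmann's bundle (CT_BB), tricuspid valve ring (TVR), right atrial
#' appendage (RAA), left atrium (LA), fossa ovalis (FO), mitral valve ring
#' (MVR), left atrial appendage (LAA), pulmonary veins (PV), coronary
#' sinus (CS).
#'
#' @return A data frame with one row per region.
#' @export
#' @examples
#' atrial_region_table()
atrial_region_table <- function() {
  data.frame(
    region = c("RA", "PM", "CT_BB", "TVR", "RAA", "LA", "FO", "MVR",
               "LAA", "PV", "CS"),
    f_gto  = c(1.00, 1.00, 1.00, 1.00, 0.68, 1.00, 1.00, 1.00, 0.68, 1.00, 1.00),
    f_gcal = c(1.00, 1.00, 1.67, 0.67, 1.00, 1.00, 1.00, 0.67, 1.00, 1.00, 1.00),
    f_gkr  = c(1.00, 1.00, 1.00, 1.53, 1.00, 1.60, 1.60, 2.44, 1.60, 2.20, 1.60),
    sigma_l = c(0.003, 0.0075, 0.0085, 0.003, 0.003, 0.003, 0.000, 0.003,
                0.003, 0.0017, 0.006),
    anisotropy = c(0.35, 0.15, 0.15, 0.35, 0.35, 0.35, 1.00, 0.35, 0.35,
                   0.5, 0.5),
    cv_l = c(63.3, 115.4, 100.0, 63.3, 63.3, 63.3, 0.0, 62.9, 63.3, 75.0, 97.2),
    stringsAsFactors = FALSE
  )
}

#' Ionic model constant records
#'
#' Reads the versioned YAML constant files shipped with the package: the
#' full parameter set of the Courtemanche-Ramirez-Nattel myocyte model and
#' of the MacCannell active fibroblast model.
#'
#' @param model `"crn"` or `"maccannell"`.
#' @return A nested list of constants.
#' @export
ionic_constants <- function(model = c("crn", "maccannell")) {
  model <- match.arg(model)
  f <- system.file("extdata",
                   paste0(if (model == "crn") "crn" else "maccannell",
                          "_constants.yaml"),
                   package = "fibrofocal")
  yaml::read_yaml(f)
}

# Tissue-level calibration constants for the 50 x 50 x 0.3 mm slab
# experiments, frozen after calibration (see the methods vignette):
#   d_healthy: monodomain diffusivity of healthy left-atrial slab tissue
#              (mm^2/ms), calibrated so a planar wavefront crosses the slab
#              in 59 ms (CV ~ 0.85 m/s).
#   d_fibroblast_factor: fibroblast-voxel diffusivity relative to healthy
#              (isotropic), chosen together with fb_density so that a
#              0.3 mm fibroblast barrier delays the wavefront by ~5%, a
#              0.6 mm barrier by ~20%, and a 0.9 mm barrier blocks.
#   fb_density: multiplier on the fibroblast membrane current density of a
#              fibroblast voxel (effective fibroblast count / surface-to-
#              volume ratio).
#' Slab calibration constants
#'
#' Frozen tissue-level constants used by the slab builders: the healthy
#' left-atrial diffusivity (mm^2/ms) calibrated to a 59 ms slab crossing
#' (~0.85 m/s), the relative fibroblast-voxel diffusivity, and the
#' fibroblast membrane current density multiplier.
#'
#' @return Named list with `d_healthy`, `d_fibroblast_factor`,
#'   `fb_anisotropy`, `fb_density`.
#' @export
slab_calibration <- function() {
  list(
    d_healthy = 0.3068,          # mm^2/ms, calibrated (59 ms anchor)
    d_fibroblast_factor = 0.25,  # fibroblast longitudinal diffusivity
    fb_anisotropy = 0.04,        # fibrotic transverse fraction (channels)
    fb_density = 3.4             # fibroblast current density multiplier
  )
}
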