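#' Tissue model for penetration simulations
#'
#' One-term compressible Ogden hyperelasticity plus the element-deletion
#' failure surrogate. The deviatoric response is set by `(ogden_mu,
#' ogden_alpha)` with small-strain shear modulus `G0 = ogden_mu`; the
#' volumetric response by `bulk_modulus`. Elements whose maximum shear strain
#' (half the difference of extreme principal logarithmic strains) exceeds
#' `deletion_threshold` are removed between increments, which is how the
#' solver lets the probe advance through the mesh.
#'
#' Two empirical constants characterise penetration resistance at the probe
#' scale and are carried per tissue preset (see the methods vignette):
#' `penetration_strength`, the saturated tip pressure for a wide blunt tip,
#' and `process_zone`, the structural length below which sharper tips cut at
#' much lower pressure.
#'
#' @param small_strain_stiffness Small-strain Young's modulus E0 in Pa
#'   (the "brain stiffness" sweep variable; 0.5-5 kPa band).
#' @param ogden_alpha Ogden exponent (dimensionless, default -4.7).
#' @param poisson Tissue Poisson ratio used to derive `ogden_mu` and the
#'   default `bulk_modulus` from E0.
#' @param bulk_modulus Override for the volumetric modulus kappa (Pa).
#' @param density kg/m^3.
#' @param deletion_threshold Maximum shear strain for element deletion
#'   (default 0.05; sensitivity range 0.01-0.25).
#' @param friction Tissue-coating Coulomb friction coefficient in `[0, 0.5]`.
#' @param penetration_strength Saturated tip penetration pressure (Pa).
#' @param process_zone Tip-sharpness length scale (m).
#' @param name Preset label.
#' @return A `pf_tissue` object.
#' @export
tissue_model <- function(small_strain_stiffness = 2.5e3,
                         ogden_alpha = -4.7,
                         poisson = 0.49,
                         bulk_modulus = NULL,
                         density = 1040,
                         deletion_threshold = 0.05,
                         friction = 0.3,
                         penetration_strength = NULL,
                         process_zone = 65e-6,
                         name = "brain") {
  E0 <- small_strain_stiffness
  if (E0 <= 0) pf_stop("pf_domain_error", "small_strain_stiffness must be > 0")
  if (deletion_threshold < 0.005 || deletion_threshold > 0.5)
    pf_stop("pf_domain_error", "deletion_threshold outside supported range")
  if (friction < 0 || friction > 0.5)
    pf_stop("pf_domain_error", "friction must be in [0, 0.5]")
  mu <- E0 / (2 * (1 + poisson))
  if (is.null(bulk_modulus)) bulk_modulus <- E0 / (3 * (1 - 2 * poisson))
  if (is.null(penetration_strength))
    penetration_strength <- .pf_cal$sigma_brain * E0 / .pf_cal$E_ref
  structure(list(name = name,
                 small_strain_stiffness = E0,
                 ogden_mu = mu, ogden_alpha = ogden_alpha,
                 bulk_modulus = bulk_modulus, poisson = poisson,
                 density = density,
                 deletion_threshold = deletion_threshold,
                 friction = friction,
                 penetration_strength = penetration_strength,
                 process_zone = process_zone),
            class = "pf_tissue")
}

# Stored penetration calibration constants (versioned; see methods vignette).
# sigma_brain: saturated tip pressure, dura-intact cortical penetration scale.
# sigma_agarose / kappa_agarose: identified once from the reference insertion
#   measurement for the 75 x 100 um coated probe in a 0.6% agarose phantom
#   (the same single-point calibration role the deletion threshold plays in
#   the full 3-D study).
# m0: process-zone length; bevel_a/bevel_p: bevel factor g = 1 - a*(theta/75)^p;
# fric_c: insertion-force friction factor 1 + fric_c * mu / 0.5.
.pf_cal <- list(version = "1.0",
                sigma_brain = 1.0e6, E_ref = 2.5e3,
                sigma_agarose = 2.91e5,
                fem_cap_shape = 1.0,
                m0 = 65e-6,
                bevel_a = 0.5, bevel_p = 3,
                fric_c = 0.12)

#' Tissue presets
#'
#' `"brain"` is the default adult cortical preset used for the cohort safety
#' factor pipeline (chick and rat outcomes are pooled over one preset, as in
#' the source experiments); `"agarose"` is the 0.6% agarose phantom whose
#' penetration resistance is anchored to the reference insertion measurement.
#'
#' @param preset `"brain"` or `"agarose"`.
#' @param ... Overrides passed to [tissue_model()].
#' @export
tissue_preset <- function(preset = c("brain", "agarose"), ...) {
  preset <- match.arg(preset)
  if (preset == "brain") {
    tissue_model(name = "brain", ...)
  } else {
    args <- list(...)
    defaults <- list(small_strain_stiffness = 3.0e3,
                     penetration_strength = .pf_cal$sigma_agarose *
                       if (!is.null(args$small_strain_stiffness))
                         args$small_strain_stiffness / 3.0e3 else 1,
                     name = "agarose")
    do.call(tissue_model, modifyList(defaults, args))
  }
}

#' Confined-compression Ogden stress at a shear-strain level
#'
#' Axial Cauchy stress magnitude of the one-term compressible Ogden material
#' in laterally confined (oedometric) compression when the maximum shear
#' strain reaches `threshold`: principal logarithmic strains are
#' `(0, 0, -2*threshold)`. This is the constitutive stress scale entering the
#' analytic insertion-force surrogate.
#'
#' @param tissue A [tissue_model()].
#' @param threshold Maximum shear strain (defaults to the tissue's deletion
#'   threshold).
#' @return Stress in Pa (positive in compression).
#' @export
ogden_confined_stress <- function(tissue, threshold = tissue$deletion_threshold) {
  e <- 2 * threshold
  lam <- c(1, 1, exp(-e))
  s <- ogden_principal_cauchy(lam, tissue$ogden_mu, tissue$ogden_alpha,
                              tissue$bulk_modulus)
  abs(s[3])
}

#' Penetration strength of a tissue at a given tip scale
#'
#' The effective tip pressure used by the analytic surrogate:
#' `sigma_crit = penetration_strength * r(threshold) * s(m)` where
#' `r` rescales the confined-compression constitutive stress relative to the
#' default deletion threshold and `s(m) = m^2 / (m^2 + m0^2)` is the
#' empirical sharpness law on the minor tip dimension `m` (thin blades cut at
#' far lower pressure than wide blunt tips).
#'
#' @param tissue A [tissue_model()].
#' @param m Minor tip dimension in metres.
#' @param threshold Deletion threshold (defaults to the tissue's).
#' @return Pressure in Pa.
#' @export
sigma_crit <- function(tissue, m, threshold = tissue$deletion_threshold) {
  r <- ogden_confined_stress(tissue, threshold) /
    ogden_confined_stress(tissue, 0.05)
  s <- m^2 / (m^2 + tissue$process_zone^2)
  tissue$penetration_strength * r * s
}

#' Bevel reduction factor for insertion force
#'
#' Monotone non-increasing factor `g(theta) = 1 - a * (theta/75)^p` applied to
#' the tip bearing pressure; shallow bevels barely reduce the insertion force
#' and an appreciable reduction requires bevels of 60 degrees or more.
#'
#' @param bevel_angle Degrees in `[0, 75]`.
#' @export
bevel_factor <- function(bevel_angle) {
  stopifnot(all(bevel_angle >= 0), all(bevel_angle <= 75))
  1 - .pf_cal$bevel_a * (bevel_angle / 75)^.pf_cal$bevel_p
}
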