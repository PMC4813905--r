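# Fast analytic surrogate for the insertion force, used for cohort pipelines
# and large design sweeps where one finite-element penetration solve per
# design point would be prohibitive:
#
#   F = A_tip * sigma_crit(tissue, m, threshold) * g(bevel) * (1 + c_f mu/0.5)
#
# sigma_crit carries the constitutive threshold scaling and the empirical
# tip-sharpness law; g() is the bevel factor; the friction factor encodes the
# weak dependence of total insertion force on the Coulomb coefficient.
# Calibration constants are stored and versioned in `.pf_cal` (see
# pf_calibration()).

#' Stored surrogate calibration constants
#'
#' @return Named list of the versioned calibration constants used by
#'   [surrogate_insertion_force()].
#' @export
pf_calibration <- function() .pf_cal

#' Analytic surrogate insertion force
#'
#' @param assembly A [coated_assembly()] (coated or uncoated; the tip is the
#'   coating footprint when coated).
#' @param tissue A [tissue_model()] or [tissue_preset()].
#' @param calibration Calibration constants; `NULL` raises a
#'   "calibration required" error.
#' @return Force in N.
#' @export
surrogate_insertion_force <- function(assembly, tissue = tissue_preset("brain"),
                                      calibration = pf_calibration()) {
  if (is.null(calibration))
    pf_stop("pf_calibration_error", "calibration required for surrogate backend")
  validate_assembly(assembly)
  ts <- tip_section(assembly)
  m <- min(ts)
  A <- ts[["t"]] * ts[["w"]]
  g <- bevel_factor(tip_bevel(assembly))
  fric <- 1 + calibration$fric_c * tissue$friction / 0.5
  A * sigma_crit(tissue, m) * g * fric
}

#' Calibrate the surrogate scale against the penetration solver
#'
#' Runs [simulate_insertion()] on a small design grid (default: three coated
#' geometries at the default bevel), fits the single multiplicative scale
#' between surrogate and solver by least squares, and reports the residuals.
#' The shipped surrogate constants are anchored to the reference experiments;
#' this function quantifies how closely the two backends agree.
#'
#' @param geometries List of `c(thickness_um, width_um, bevel_deg)` coatings
#'   applied to the default Parylene C shank.
#' @param tissue Tissue model (default agarose).
#' @param mesh Mesh level for the solver runs.
#' @return List with `scale`, `residuals` (fractional, per grid point),
#'   `fem_mN`, `surrogate_mN`.
#' @export
calibrate_surrogate <- function(geometries = list(c(75, 100, 45),
                                                  c(100, 100, 45),
                                                  c(75, 100, 20)),
                                tissue = tissue_preset("agarose"),
                                mesh = "default") {
  probe <- probe_spec(20, 5, 3500, "parylene_c")
  fem <- sur <- numeric(length(geometries))
  for (i in seq_along(geometries)) {
    g <- geometries[[i]]
    asm <- coated_assembly(probe, coating_spec(g[1], g[2], 4000,
                                               bevel_angle = g[3]))
    fem[i] <- simulate_insertion(asm, tissue, mesh = mesh)$insertion_force
    sur[i] <- surrogate_insertion_force(asm, tissue)
  }
  sc <- sum(fem * sur) / sum(sur^2)
  list(scale = sc, residuals = (sc * sur - fem) / fem,
       fem_mN = mN(fem), surrogate_mN = mN(sur))
}

#' Sensitivity of insertion force to model parameters
#'
#' Re-runs the insertion prediction at each supplied value of one parameter
#' and reports the percent change relative to the default-parameter run.
#'
#' @param assembly,tissue As in [surrogate_insertion_force()].
#' @param parameter One of `"bulk_modulus"`, `"friction"`,
#'   `"deletion_threshold"`, `"material"` (scales the tissue stiffness, e.g.
#'   +/-10%).
#' @param values Parameter values (for `"material"`, multiplicative factors
#'   such as `c(0.9, 1, 1.1)`).
#' @param backend `"fem"` (runs [simulate_insertion()]) or `"surrogate"`.
#' @param ... Extra arguments passed to [simulate_insertion()].
#' @return Data frame (value, insertion_force_mN, pct_change).
#' @export
sensitivity_sweep <- function(assembly, tissue = tissue_preset("agarose"),
                              parameter = c("deletion_threshold", "friction",
                                            "bulk_modulus", "material"),
                              values,
                              backend = c("fem", "surrogate"), ...) {
  parameter <- match.arg(parameter)
  backend <- match.arg(backend)
  run <- function(tis) {
    if (backend == "fem") simulate_insertion(assembly, tis, ...)$insertion_force
    else surrogate_insertion_force(assembly, tis)
  }
  vary <- function(v) {
    t2 <- tissue
    if (parameter == "material") {
      t2$ogden_mu <- t2$ogden_mu * v
      t2$bulk_modulus <- t2$bulk_modulus * v
      t2$small_strain_stiffness <- t2$small_strain_stiffness * v
      t2$penetration_strength <- t2$penetration_strength * v
    } else t2[[parameter]] <- v
    t2
  }
  F0 <- run(tissue)
  out <- lapply(values, function(v) {
    Fi <- tryCatch(run(vary(v)), error = function(e) {
      warning(sprintf("%s = %g failed: %s", parameter, v, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
    data.frame(value = v, insertion_force_mN = mN(Fi),
               pct_change = 100 * (Fi - F0) / F0)
  })
  res <- do.call(rbind, out)
  attr(res, "default_force_mN") <- mN(F0)
  res
}
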