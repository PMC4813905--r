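#' Construct a material
#'
#' A material is the elastic description used by both the buckling and the
#' penetration models: flexural (bending) modulus, density and Poisson ratio.
#'
#' @param name Character label.
#' @param modulus Flexural modulus in Pa.
#' @param density Density in kg/m^3.
#' @param poisson Poisson ratio, in `[0, 0.5)`.
#' @return An object of class `pf_material`.
#' @export
material <- function(name, modulus, density, poisson) {
  if (!is.numeric(modulus) || modulus <= 0)
    pf_stop("pf_domain_error", "material '%s': modulus must be > 0", name)
  if (!is.numeric(density) || density <= 0)
    pf_stop("pf_domain_error", "material '%s': density must be > 0", name)
  if (!is.numeric(poisson) || poisson < 0 || poisson >= 0.5)
    pf_stop("pf_domain_error", "material '%s': poisson must be in [0, 0.5)", name)
  structure(list(name = name, modulus = modulus, density = density,
                 poisson = poisson), class = "pf_material")
}

#' @export
print.pf_material <- function(x, ...) {
  cat(sprintf("<material %s>  E = %.4g Pa, rho = %.4g kg/m^3, nu = %.3g\n",
              x$name, x$modulus, x$density, x$poisson))
  invisible(x)
}

#' Built-in material library
#'
#' Returns the four materials used throughout the probe/coating studies:
#' copper wire mimics, SU-8 photoresist probes, Parylene C probes, and the
#' sacrificial tyrosine-derived polycarbonate coating. Flexural moduli for the
#' two polymers were characterised by self-weight cantilever deflection (see
#' [flexural_modulus()]); the remaining constants are literature values.
#'
#' @param extra Optional named list of additional [material()] objects, or a
#'   path to a YAML/JSON file with entries `name: {modulus, density, poisson}`
#'   (moduli in Pa) which are added to (or override) the built-ins.
#' @return Named list of `pf_material`.
#' @examples
#' lib <- material_library()
#' lib$parylene_c$modulus   # 5.6e6 Pa
#' @export
material_library <- function(extra = NULL) {
  lib <- list(
    copper     = material("copper",     110e9,  8960, 0.36),
    su8        = material("su8",        2.4e9,  1190, 0.32),
    parylene_c = material("parylene_c", 5.6e6,  1289, 0.45),
    coating    = material("coating",    1.9e9,  1290, 0.42)
  )
  if (is.character(extra)) extra <- read_material_overrides(extra)
  if (!is.null(extra)) {
    stopifnot(is.list(extra))
    for (nm in names(extra)) {
      e <- extra[[nm]]
      if (!inherits(e, "pf_material"))
        e <- material(nm, e$modulus, e$density, e$poisson)
      lib[[nm]] <- e
    }
  }
  lib
}

read_material_overrides <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(e) e)
}

resolve_material <- function(m, library = material_library()) {
  if (inherits(m, "pf_material")) return(m)
  if (is.character(m)) {
    if (!m %in% names(library))
      pf_stop("pf_domain_error", "unknown material '%s'", m)
    return(library[[m]])
  }
  pf_stop("pf_domain_error", "material must be a pf_material or a library name")
}
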