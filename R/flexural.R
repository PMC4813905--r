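# Flexural-modulus identification from self-weight cantilever deflection.
# A thin polymer strip clamped at one end sags under its own weight; the
# linear beam deflection formula delta_max = q L^4 / (8 E I) is inverted to
# recover the flexural modulus E (this is how the SU-8 and Parylene C moduli
# in the material library were characterised).

.g0 <- 9.81  # m/s^2

#' Flexural modulus from a self-weight deflection measurement
#'
#' Inverts `E = q L^4 / (8 I delta_max)`.
#'
#' @param strip_length Strip length L in metres.
#' @param weight_per_length Weight per unit length q in N/m.
#' @param second_moment Area moment of inertia I in m^4 (for a flat strip
#'   bending about its thin axis, `width * thickness^3 / 12`).
#' @param max_deflection Measured tip deflection in metres.
#' @return Flexural modulus in Pa. Warns if the deflection is large relative
#'   to the strip length (small-deflection formula no longer valid).
#' @export
flexural_modulus <- function(strip_length, weight_per_length, second_moment,
                             max_deflection) {
  vals <- c(strip_length, weight_per_length, second_moment, max_deflection)
  if (any(!is.finite(vals)) || any(vals <= 0))
    pf_stop("pf_domain_error", "all measurement fields must be positive")
  if (max_deflection >= strip_length)
    warning("deflection >= strip length: small-deflection formula invalid",
            call. = FALSE)
  weight_per_length * strip_length^4 / (8 * second_moment * max_deflection)
}

#' Self-weight cantilever deflection of a flat strip (forward model)
#'
#' `delta_max = q L^4 / (8 E I)` with `q = rho g width thickness` and
#' `I = width thickness^3 / 12`.
#'
#' @param length,width,thickness Strip dimensions in metres.
#' @param material A [material()] (supplies E and rho), or supply `modulus`
#'   and `density` directly.
#' @param modulus,density Optional scalar overrides (Pa, kg/m^3).
#' @return Tip deflection in metres.
#' @export
self_weight_deflection <- function(length, width, thickness, material = NULL,
                                   modulus = material$modulus,
                                   density = material$density) {
  if (any(c(length, width, thickness, modulus, density) <= 0))
    pf_stop("pf_domain_error", "strip dimensions and properties must be positive")
  q <- density * .g0 * width * thickness
  I <- width * thickness^3 / 12
  q * length^4 / (8 * modulus * I)
}

#' Batch flexural-modulus report from a measurement CSV
#'
#' @param path CSV with columns `length_m, width_m, thickness_m, density,
#'   deflection_m`.
#' @return Data frame with per-strip modulus plus attributes `mean` and `sd`.
#' @export
read_deflection_batch <- function(path) {
  df <- read.csv(path)
  need <- c("length_m", "width_m", "thickness_m", "density", "deflection_m")
  if (!all(need %in% names(df)))
    pf_stop("pf_config_error", "missing columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  df$modulus_Pa <- mapply(function(L, w, t, rho, d) {
    q <- rho * .g0 * w * t
    flexural_modulus(L, q, w * t^3 / 12, d)
  }, df$length_m, df$width_m, df$thickness_m, df$density, df$deflection_m)
  attr(df, "mean") <- mean(df$modulus_Pa)
  attr(df, "sd") <- sd(df$modulus_Pa)
  df
}
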