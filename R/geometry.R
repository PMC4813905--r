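#' Probe specification
#'
#' @param width,thickness,length Dimensions in micrometres. For rectangular
#'   probes `width >= thickness` is the usual convention (width x thickness x
#'   length, e.g. 320 x 5 x 3500).
#' @param material A [material()] or a library name.
#' @param shape `"rectangular"` or `"circular"`; circular probes (wire mimics)
#'   take `diameter` instead of width/thickness.
#' @param diameter Diameter in micrometres (circular only).
#' @return A `pf_probe` object (lengths stored in metres).
#' @export
probe_spec <- function(width = NULL, thickness = NULL, length,
                       material, shape = c("rectangular", "circular"),
                       diameter = NULL) {
  shape <- match.arg(shape)
  material <- resolve_material(material)
  if (shape == "circular") {
    if (is.null(diameter) || diameter <= 0)
      pf_stop("pf_domain_error", "circular probe needs diameter > 0")
    width <- thickness <- diameter
  }
  if (any(c(width, thickness, length) <= 0))
    pf_stop("pf_domain_error", "probe dimensions must be > 0")
  if (length < max(width, thickness))
    pf_stop("pf_domain_error", "probe length must be >= max(width, thickness)")
  structure(list(width = um_to_m(width), thickness = um_to_m(thickness),
                 length = um_to_m(length), material = material, shape = shape,
                 diameter = if (shape == "circular") um_to_m(diameter)),
            class = "pf_probe")
}

#' Coating specification
#'
#' Transverse dimensions are the *overall* cross-section of the beveled
#' sacrificial coating: `thickness` is the smaller transverse dimension (the
#' design sweep variable), `width` the larger. The beveled tip belongs to the
#' coating, which fully encapsulates the probe.
#'
#' @param thickness,width,length Overall dimensions in micrometres.
#' @param bevel_angle Tip bevel angle in degrees, in `[0, 75]`.
#' @param material A [material()] or library name (default the sacrificial
#'   tyrosine polycarbonate).
#' @return A `pf_coating` object (lengths stored in metres).
#' @export
coating_spec <- function(thickness, width, length, bevel_angle = 45,
                         material = "coating") {
  if (any(c(thickness, width, length) <= 0))
    pf_stop("pf_domain_error", "coating dimensions must be > 0")
  if (bevel_angle < 0 || bevel_angle > 75)
    pf_stop("pf_domain_error", "bevel_angle must be in [0, 75] degrees")
  structure(list(thickness = um_to_m(thickness), width = um_to_m(width),
                 length = um_to_m(length), bevel_angle = bevel_angle,
                 material = resolve_material(material)),
            class = "pf_coating")
}

#' Coated (or uncoated) probe assembly
#'
#' @param probe A [probe_spec()].
#' @param coating A [coating_spec()] or `NULL` for an uncoated probe.
#' @param insertion_angle Degrees from the tissue surface normal (default 0).
#' @return A validated `pf_assembly`.
#' @export
coated_assembly <- function(probe, coating = NULL, insertion_angle = 0) {
  a <- structure(list(probe = probe, coating = coating,
                      insertion_angle = insertion_angle),
                 class = "pf_assembly")
  validate_assembly(a)
}

#' Encapsulate a probe in a uniform coating layer
#'
#' Convenience constructor mirroring the fabrication process: a layer of
#' thickness `layer` um is applied on each side, so the overall coating
#' cross-section is `(thickness + 2*layer) x (width + 2*layer)`.
#'
#' @inheritParams coated_assembly
#' @param layer Per-side layer thickness in micrometres.
#' @param length Coating length in micrometres (default probe length + 500).
#' @param bevel_angle,material Passed to [coating_spec()].
#' @export
coat_probe <- function(probe, layer, length = NULL, bevel_angle = 45,
                       material = "coating") {
  if (layer < 0) pf_stop("pf_domain_error", "layer must be >= 0")
  if (is.null(length)) length <- m_to_um(probe$length) + 500
  coated_assembly(probe, coating_spec(
    thickness = m_to_um(probe$thickness) + 2 * layer,
    width = m_to_um(probe$width) + 2 * layer,
    length = length, bevel_angle = bevel_angle, material = material))
}

#' Validate an assembly's geometric invariants
#'
#' Checks that all dimensions are positive and, for coated assemblies, that
#' the coating cross-section fully encloses the probe cross-section and the
#' coating is at least as long as the probe (perfect bonding between coating
#' and probe is assumed throughout).
#'
#' @param assembly A `pf_assembly`.
#' @return The assembly, invisibly checked.
#' @export
validate_assembly <- function(assembly) {
  p <- assembly$probe; cc <- assembly$coating
  if (!inherits(p, "pf_probe")) pf_stop("pf_domain_error", "probe missing")
  if (!is.null(cc)) {
    if (cc$thickness < p$thickness || cc$width < p$width)
      pf_stop("pf_geometry_error",
              "coating cross-section (%g x %g um) does not enclose probe (%g x %g um)",
              m_to_um(cc$thickness), m_to_um(cc$width),
              m_to_um(p$thickness), m_to_um(p$width))
    if (cc$length < p$length)
      pf_stop("pf_geometry_error", "coating shorter than probe")
  }
  assembly
}

is_coated <- function(assembly) !is.null(assembly$coating)

# governing column length and tip cross-section (m): the coating carries the
# load when present
assembly_length <- function(a) if (is_coated(a)) a$coating$length else a$probe$length

tip_section <- function(a) {
  if (is_coated(a)) c(t = a$coating$thickness, w = a$coating$width)
  else c(t = a$probe$thickness, w = a$probe$width)
}

tip_bevel <- function(a) if (is_coated(a)) a$coating$bevel_angle else 45

#' @export
print.pf_assembly <- function(x, ...) {
  p <- x$probe
  cat(sprintf("<assembly> probe %s %g x %g x %g um",
              p$material$name, m_to_um(p$width), m_to_um(p$thickness),
              m_to_um(p$length)))
  if (is_coated(x)) {
    cc <- x$coating
    cat(sprintf(" | coating %g x %g x %g um, bevel %g deg",
                m_to_um(cc$thickness), m_to_um(cc$width), m_to_um(cc$length),
                cc$bevel_angle))
  } else cat(" | uncoated")
  cat("\n"); invisible(x)
}
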