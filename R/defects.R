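# Coating-defect model: a cylindrical void in the sacrificial coating,
# parameterized by its radius as a proportion of the coating thickness and by
# its site. Voids enter the buckling path as reduced section properties over
# a finite axial window (window length = void diameter); voids at the beveled
# tip additionally blunt the tip (the divot destroys the bevel over the void
# diameter), raising the insertion force. Side voids away from the tip leave
# the insertion force unchanged.

#' Cylindrical coating void descriptor
#'
#' @param radius_fraction Void radius as a fraction of the coating thickness,
#'   in `[0.05, 1]`.
#' @param site `"tip"` (at the beveled tip) or `"side"` (along the shank).
#' @param axial_position_um Distance of the void centre from the tip, in um
#'   (defaults to the void radius for tip voids, mid-length for side voids;
#'   must lie within the coating).
#' @return A `pf_defect`.
#' @export
void_defect <- function(radius_fraction, site = c("tip", "side"),
                        axial_position_um = NULL) {
  site <- match.arg(site)
  if (radius_fraction < 0.05 || radius_fraction > 1)
    pf_stop("pf_domain_error", "radius_fraction must be in [0.05, 1]")
  structure(list(radius_fraction = radius_fraction, site = site,
                 axial_position_um = axial_position_um), class = "pf_defect")
}

# reduced flexural rigidity of the voided coating cross-section.
# Exact when the circle fits inside the section; otherwise the circle is
# clipped to the rectangle by numeric integration.
voided_section_EI <- function(assembly, r) {
  cc <- assembly$coating
  base_ab <- section_EI_axes(assembly)
  weak <- which.min(base_ab)
  t <- cc$thickness; w <- cc$width; Ec <- cc$material$modulus
  if (2 * r <= min(t, w)) {
    Iv <- pi * r^4 / 4
  } else {
    n <- 400
    ys <- (seq_len(n) - 0.5) / n * t - t / 2   # weak-axis coordinate
    xs <- (seq_len(n) - 0.5) / n * w - w / 2
    dA <- (t / n) * (w / n)
    yy <- matrix(ys, n, n); xx <- matrix(xs, n, n, byrow = TRUE)
    inside <- (xx^2 + yy^2) <= r^2
    coord2 <- if (weak == 1) yy^2 else xx^2
    Iv <- sum(coord2[inside]) * dA
  }
  Iv <- min(Iv, rect_I(w, t) * 0.999)  # cannot remove more than the section
  unname(base_ab[weak] - Ec * Iv)
}

#' Apply a void defect to an assembly
#'
#' @param assembly A coated [coated_assembly()].
#' @param defect A [void_defect()].
#' @return A `pf_defective` descriptor holding the base assembly, the void
#'   radius (m), the axial window over which the coating section is reduced,
#'   the reduced window rigidity, and the tip blunting fraction.
#' @export
apply_defect <- function(assembly, defect) {
  validate_assembly(assembly)
  if (!is_coated(assembly))
    pf_stop("pf_geometry_error", "defects apply to coated assemblies")
  cc <- assembly$coating
  r <- defect$radius_fraction * cc$thickness
  if (2 * r > 2 * cc$thickness)
    pf_stop("pf_geometry_error", "void larger than coating")
  L <- cc$length
  pos <- if (!is.null(defect$axial_position_um)) um_to_m(defect$axial_position_um)
         else if (defect$site == "tip") r else L / 2
  if (pos < 0 || pos > L)
    pf_stop("pf_geometry_error", "axial position outside coating")
  blunt <- if (defect$site == "tip") min(1, 2 * r / cc$thickness) else 0
  structure(list(assembly = assembly, defect = defect, radius = r,
                 window = c(max(0, pos - r), min(L, pos + r)),  # from tip
                 EI_window = voided_section_EI(assembly, r),
                 blunt_fraction = blunt),
            class = "pf_defective")
}

defective_buckling_force <- function(dd, bc = "fixed_pinned", n_elements = 400) {
  a <- dd$assembly
  L <- assembly_length(a)
  EI_full <- composite_section(a)$flexural_rigidity
  xe <- (seq_len(n_elements) - 0.5) / n_elements * L  # from actuator end
  from_tip <- L - xe
  EI <- ifelse(from_tip >= dd$window[1] & from_tip <= dd$window[2],
               min(dd$EI_window, EI_full), EI_full)
  fe_buckling(EI = EI, length = L, bc = bc)$critical_force
}

defective_insertion_force <- function(dd, tissue) {
  a <- dd$assembly
  F0 <- surrogate_insertion_force(a, tissue)
  g0 <- bevel_factor(tip_bevel(a))
  g_eff <- g0 + dd$blunt_fraction * (1 - g0)
  F0 * g_eff / g0
}

#' Predict forces and safety factor for a defective assembly
#'
#' @param dd A `pf_defective` from [apply_defect()].
#' @param tissue A [tissue_model()].
#' @param bc Buckling boundary condition.
#' @return `pf_prediction` as in [predict_insertion()].
#' @export
predict_defective <- function(dd, tissue = tissue_preset("brain"),
                              bc = "fixed_pinned") {
  Fb <- defective_buckling_force(dd, bc = bc)
  Fi <- defective_insertion_force(dd, tissue)
  structure(list(buckling_force = Fb, insertion_force = Fi,
                 safety_factor = Fb / Fi, backend = "surrogate", bc = bc,
                 predicted_probability = NULL), class = "pf_prediction")
}

#' Defect sensitivity over coating thicknesses, void sizes and sites
#'
#' For each combination, the percentage change in buckling force, insertion
#' force and safety factor relative to the defect-free baseline of the same
#' coating thickness.
#'
#' @param probe The flexible probe (default the 20 x 5 x 3500 um Parylene C
#'   shank used throughout the defect study).
#' @param tissue Tissue model.
#' @param coating_thicknesses_um Coating thicknesses (um).
#' @param coating_width_um Coating width (um).
#' @param fractions Void radius fractions, or `NULL` with `void_diameter_um`.
#' @param void_diameter_um Fixed void diameter applied across thicknesses
#'   (radius fraction computed per thickness).
#' @param sites Defect sites.
#' @param bc Buckling boundary condition.
#' @return Data frame with columns `coating_t_um, site, radius_fraction,
#'   pct_dF_buckle, pct_dF_insert, pct_dSF`.
#' @export
defect_sensitivity <- function(probe = probe_spec(20, 5, 3500, "parylene_c"),
                               tissue = tissue_preset("brain"),
                               coating_thicknesses_um = c(50, 75, 100, 200),
                               coating_width_um = 100,
                               fractions = c(0.05, 0.125, 0.25, 0.5),
                               void_diameter_um = NULL,
                               sites = c("tip", "side"),
                               bc = "fixed_pinned") {
  rows <- list()
  for (tc in coating_thicknesses_um) {
    cw <- max(coating_width_um, m_to_um(probe$width))
    asm <- coated_assembly(probe, coating_spec(tc, cw, 4000))
    # baseline via the same FE discretization to cancel discretization bias
    base_dd <- apply_defect(asm, void_defect(0.05, "side"))
    base_dd$EI_window <- composite_section(asm)$flexural_rigidity
    base_dd$blunt_fraction <- 0
    Fb0 <- defective_buckling_force(base_dd, bc = bc)
    Fi0 <- surrogate_insertion_force(asm, tissue)
    fr <- if (!is.null(void_diameter_um)) (void_diameter_um / 2) / tc
          else fractions
    fr <- fr[fr >= 0.05 & fr <= 1]
    for (site in sites) for (f in fr) {
      dd <- apply_defect(asm, void_defect(f, site))
      Fb <- defective_buckling_force(dd, bc = bc)
      Fi <- defective_insertion_force(dd, tissue)
      rows[[length(rows) + 1]] <- data.frame(
        coating_t_um = tc, site = site, radius_fraction = f,
        pct_dF_buckle = 100 * (Fb - Fb0) / Fb0,
        pct_dF_insert = 100 * (Fi - Fi0) / Fi0,
        pct_dSF = 100 * (Fb / Fi - Fb0 / Fi0) / (Fb0 / Fi0))
    }
  }
  do.call(rbind, rows)
}
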