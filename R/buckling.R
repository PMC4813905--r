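# Critical buckling load of the coated probe column: composite-section Euler
# theory (perfect probe-coating bonding justifies the transformed-section
# rule, rigidity = sum of E_i I_i about the shared centroid) and a
# finite-element Euler-Bernoulli beam eigensolver for stepped sections.

.bc_K <- c(fixed_free = 2.0, fixed_pinned = 0.6992,
           pinned_pinned = 1.0, fixed_fixed = 0.5)

rect_I <- function(w, t) w * t^3 / 12  # bending about axis parallel to w

section_EI_axes <- function(assembly) {
  p <- assembly$probe
  Ip_a <- if (p$shape == "circular") pi * p$diameter^4 / 64 else
    rect_I(p$width, p$thickness)
  Ip_b <- if (p$shape == "circular") Ip_a else rect_I(p$thickness, p$width)
  Ep <- p$material$modulus
  if (!is_coated(assembly))
    return(c(a = Ep * Ip_a, b = Ep * Ip_b))
  cc <- assembly$coating; Ec <- cc$material$modulus
  Ic_a <- rect_I(cc$width, cc$thickness) - Ip_a
  Ic_b <- rect_I(cc$thickness, cc$width) - Ip_b
  c(a = Ec * Ic_a + Ep * Ip_a, b = Ec * Ic_b + Ep * Ip_b)
}

#' Composite transformed section of an assembly
#'
#' Flexural rigidity about the weak bending axis (the lowest critical load
#' governs). For coated assemblies the coating contributes the enclosing
#' rectangle minus the probe footprint; the probe contributes its own section;
#' both are weighted by their moduli.
#'
#' @param assembly A [coated_assembly()].
#' @return A `pf_section`: `flexural_rigidity` (N m^2), per-constituent
#'   segments, and rigidities about both axes.
#' @export
composite_section <- function(assembly) {
  validate_assembly(assembly)
  ab <- section_EI_axes(assembly)
  p <- assembly$probe
  segs <- list(list(material = p$material$name,
                    area = if (p$shape == "circular") pi * p$diameter^2 / 4
                           else p$width * p$thickness))
  if (is_coated(assembly)) {
    cc <- assembly$coating
    segs <- c(segs, list(list(material = cc$material$name,
                              area = cc$thickness * cc$width - segs[[1]]$area)))
  }
  structure(list(flexural_rigidity = min(ab), rigidity_axes = ab,
                 segments = segs), class = "pf_section")
}

#' Euler critical buckling force
#'
#' `F = pi^2 (sum E I) / (K L)^2` with effective-length factor K of 2.0
#' (fixed-free), 0.6992 (fixed-pinned), 1.0 (pinned-pinned) or 0.5
#' (fixed-fixed). The default boundary condition throughout the package is
#' fixed-pinned: top clamped to the actuator, tip bearing on the tissue.
#'
#' @param section A `pf_section` (or a bare rigidity in N m^2).
#' @param length Column length in metres.
#' @param bc Boundary condition.
#' @return Critical force in N.
#' @export
euler_critical_force <- function(section, length,
                                 bc = c("fixed_pinned", "fixed_free",
                                        "pinned_pinned", "fixed_fixed")) {
  bc <- match.arg(bc)
  EI <- if (inherits(section, "pf_section")) section$flexural_rigidity else section
  if (length <= 0) pf_stop("pf_domain_error", "length must be > 0")
  pi^2 * EI / (.bc_K[[bc]] * length)^2
}

# Hermite-cubic beam element matrices with rotation dofs scaled by the
# element length (theta_hat = theta * L): a congruence transform that leaves
# the buckling eigenvalues unchanged and keeps the assembled matrices well
# conditioned at fine discretizations
.beam_ke <- function(EI, L) {
  EI / L^3 * matrix(c(12, 6, -12, 6,
                      6, 4, -6, 2,
                      -12, -6, 12, -6,
                      6, 2, -6, 4), 4, 4)
}
.beam_kg <- function(L) {
  1 / (30 * L) * matrix(c(36, 3, -36, 3,
                          3, 4, -3, -1,
                          -36, -3, 36, -3,
                          3, -1, -3, 4), 4, 4)
}

bc_fixed_dofs <- function(bc, n_nodes) {
  # dof order: (w_1, th_1, ..., w_n, th_n); node 1 = actuator end, node n = tip
  top <- c(1, 2); tip_w <- 2 * n_nodes - 1; tip_th <- 2 * n_nodes
  switch(bc,
         fixed_free = top,
         fixed_pinned = c(top, tip_w),
         pinned_pinned = c(1, tip_w),
         fixed_fixed = c(top, tip_w, tip_th))
}

#' Finite-element linear buckling of a (possibly stepped) column
#'
#' Solves the generalized eigenproblem between the elastic stiffness and the
#' geometric (initial-stress) stiffness of an axially loaded Euler-Bernoulli
#' beam discretization; the smallest positive eigenvalue is the critical
#' force. Coated assemblies are stepped automatically: composite section over
#' the probed region, coating-only section beyond the probe tip.
#'
#' @param assembly A [coated_assembly()], or `NULL` when `EI` is given.
#' @param bc Boundary condition (default fixed-pinned).
#' @param n_elements Number of beam elements (>= 4).
#' @param EI Optional explicit per-element rigidity vector (N m^2) paired
#'   with `length`; overrides `assembly`.
#' @param length Column length in metres (required with `EI`).
#' @return A `pf_buckling` with `critical_force` (N), `mode_shape` (data
#'   frame x, w), `bc`, `n_elements`.
#' @export
fe_buckling <- function(assembly = NULL,
                        bc = c("fixed_pinned", "fixed_free",
                               "pinned_pinned", "fixed_fixed"),
                        n_elements = 100, EI = NULL, length = NULL) {
  bc <- match.arg(bc)
  if (n_elements < 4) pf_stop("pf_domain_error", "n_elements must be >= 4")
  if (is.null(EI)) {
    validate_assembly(assembly)
    length <- assembly_length(assembly)
    xe <- (seq_len(n_elements) - 0.5) / n_elements * length
    EI_full <- composite_section(assembly)$flexural_rigidity
    if (is_coated(assembly)) {
      EI_coat_only <- {  # region beyond the probe tip
        cc <- assembly$coating
        min(cc$material$modulus * rect_I(cc$width, cc$thickness),
            cc$material$modulus * rect_I(cc$thickness, cc$width))
      }
      EI <- ifelse(xe <= assembly$probe$length, EI_full, EI_coat_only)
    } else EI <- rep(EI_full, n_elements)
  } else {
    if (is.null(length)) pf_stop("pf_domain_error", "length required with EI")
    if (base::length(EI) == 1) EI <- rep(EI, n_elements)
    n_elements <- base::length(EI)
  }
  if (any(EI <= 0)) pf_stop("pf_domain_error", "EI must be positive")
  n_nodes <- n_elements + 1
  Le <- length / n_elements
  ndof <- 2 * n_nodes
  K <- matrix(0, ndof, ndof); G <- matrix(0, ndof, ndof)
  for (e in seq_len(n_elements)) {
    idx <- (2 * e - 1):(2 * e + 2)
    K[idx, idx] <- K[idx, idx] + .beam_ke(EI[e], Le)
    G[idx, idx] <- G[idx, idx] + .beam_kg(Le)
  }
  fixed <- bc_fixed_dofs(bc, n_nodes)
  keep <- setdiff(seq_len(ndof), fixed)
  A <- solve(K[keep, keep], G[keep, keep])
  ev <- eigen(A)
  mu <- Re(ev$values)
  ok <- which(abs(Im(ev$values)) < 1e-8 * max(abs(ev$values)) & mu > 0)
  if (!base::length(ok))
    pf_stop("pf_numerical_error", "no positive buckling eigenvalue found")
  i <- ok[which.max(mu[ok])]
  Pcr <- 1 / mu[i]
  phi <- numeric(ndof); phi[keep] <- Re(ev$vectors[, i])
  w <- phi[seq(1, ndof, by = 2)]
  w <- w / max(abs(w))
  structure(list(critical_force = Pcr,
                 mode_shape = data.frame(x = seq(0, length, length.out = n_nodes),
                                         w = w),
                 bc = bc, n_elements = n_elements), class = "pf_buckling")
}

#' Buckling force of an assembly (closed form)
#'
#' Composite-section Euler critical load about the weak axis; the default
#' fast path used by the safety-factor pipeline and design sweeps.
#'
#' @inheritParams fe_buckling
#' @return Force in N.
#' @export
buckling_force <- function(assembly, bc = "fixed_pinned") {
  euler_critical_force(composite_section(assembly), assembly_length(assembly),
                       bc = bc)
}
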