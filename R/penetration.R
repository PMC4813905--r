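# Reduced-dimension penetration solver.
#
# The coated probe tip is modeled as a rigid beveled punch (coating modulus
# exceeds the tissue modulus by ~6 orders of magnitude) advancing
# quasi-statically into a 2-D plane-strain tissue block meshed with fully
# integrated bilinear quadrilaterals. The in-plane direction carries the
# minor tip dimension; forces are scaled by the major tip dimension
# (out-of-plane width). Tissue is one-term compressible Ogden; after each
# converged displacement increment, every element whose maximum shear strain
# exceeds the deletion threshold is removed before the next increment, which
# is how the punch advances through the mesh. Contact is a node-to-surface
# penalty with Coulomb friction; the bottom of the block and the far side
# edges are fixed (the enlarged domain stands in for far-field elements).

.gp1 <- 1 / sqrt(3)
.quad_gp <- cbind(xi = c(-.gp1, .gp1, .gp1, -.gp1),
                  eta = c(-.gp1, -.gp1, .gp1, .gp1))

.shape_grad <- function(xi, eta) {
  # columns: nodes (-1,-1),(1,-1),(1,1),(-1,1); rows: d/dxi, d/deta
  rbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

build_tissue_mesh <- function(tip_w, depth, h, domain_factor = 20) {
  half_tip <- tip_w / 2
  # fine zone around the punch, geometric grading to the far edge
  xf <- seq(0, half_tip + 2 * h, by = h)
  xg <- xf[length(xf)]
  while (xg < domain_factor * tip_w / 2) {
    step <- min(1.6 * (xg - xf[length(xf) - 1]), domain_factor * tip_w / 8)
    xg <- xg + step
    xf <- c(xf, xg)
  }
  xs <- c(-rev(xf[-1]), xf)
  yf <- seq(0, depth + 3 * h, by = h)
  yg <- yf[length(yf)]
  H <- max(2 * depth, depth + 10 * h)
  while (yg < H) {
    step <- min(1.6 * (yg - yf[length(yf) - 1]), H / 4)
    yg <- yg + step
    yf <- c(yf, yg)
  }
  ys <- rev(-yf)                       # bottom ... 0 (surface)
  nxn <- length(xs); nyn <- length(ys)
  nx <- nxn - 1; ny <- nyn - 1
  X <- cbind(rep(xs, times = nyn), rep(ys, each = nxn))
  nid <- function(i, j) (j - 1) * nxn + i
  ii <- rep(seq_len(nx), times = ny); jj <- rep(seq_len(ny), each = nx)
  elem <- cbind(nid(ii, jj), nid(ii + 1, jj), nid(ii + 1, jj + 1), nid(ii, jj + 1))
  dx <- xs[ii + 1] - xs[ii]; dy <- ys[jj + 1] - ys[jj]
  fixed_nodes <- unique(c(nid(seq_len(nxn), 1),            # bottom
                          nid(1, seq_len(nyn)), nid(nxn, seq_len(nyn))))
  list(xs = xs, ys = ys, nxn = nxn, nyn = nyn, X = X, elem = elem,
       dx = dx, dy = dy, nel = nx * ny, nnode = nxn * nyn,
       fixed_nodes = fixed_nodes, h = h)
}

# linear plane-strain element stiffness for a dx-by-dy rectangle
.ke_rect <- function(dx, dy, mu, lam) {
  D <- matrix(c(lam + 2 * mu, lam, 0, lam, lam + 2 * mu, 0, 0, 0, mu), 3, 3)
  ke <- matrix(0, 8, 8)
  for (g in seq_len(4)) {
    dN <- .shape_grad(.quad_gp[g, 1], .quad_gp[g, 2])
    dNx <- dN[1, ] * 2 / dx; dNy <- dN[2, ] * 2 / dy
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNx
    B[2, seq(2, 8, 2)] <- dNy
    B[3, seq(1, 8, 2)] <- dNy
    B[3, seq(2, 8, 2)] <- dNx
    ke <- ke + t(B) %*% D %*% B * (dx * dy / 4)
  }
  ke
}

assemble_Kel <- function(mesh, alive, mu, lam) {
  sizes <- paste(signif(mesh$dx, 10), signif(mesh$dy, 10))
  usz <- !duplicated(sizes)
  kes <- lapply(which(usz), function(e) .ke_rect(mesh$dx[e], mesh$dy[e], mu, lam))
  names(kes) <- sizes[usz]
  el <- which(alive)
  nA <- length(el)
  edof <- matrix(0L, nA, 8)
  edof[, seq(1, 8, 2)] <- 2L * mesh$elem[el, ] - 1L
  edof[, seq(2, 8, 2)] <- 2L * mesh$elem[el, ]
  iidx <- matrix(0L, nA, 64); jidx <- matrix(0L, nA, 64); xval <- matrix(0, nA, 64)
  ke_stack <- t(vapply(sizes[el], function(s) as.vector(kes[[s]]), numeric(64)))
  for (a in 1:8) for (b in 1:8) {
    k <- (b - 1) * 8 + a
    iidx[, k] <- edof[, a]; jidx[, k] <- edof[, b]
  }
  xval <- ke_stack
  Matrix::sparseMatrix(i = as.vector(iidx), j = as.vector(jidx),
                       x = as.vector(xval), dims = c(2 * mesh$nnode, 2 * mesh$nnode))
}

# per-element local internal force vectors (nel x 8), total Lagrangian.
# Stabilized selective reduced integration: the deviatoric Ogden part is
# integrated at the 2x2 Gauss points; the volumetric part mostly at the
# element centroid (mean dilatation, which avoids volumetric locking of the
# bilinear quad at near-incompressible moduli), with a small fraction
# .sri_stab kept at the Gauss points to restrain the hourglass modes that a
# pure one-point volumetric rule leaves almost unresisted when mu << kappa.
.sri_stab <- 0.2

local_element_forces <- function(ux, uy, dxe, dye, mu, alpha, kappa) {
  dV <- dxe * dye / 4
  floc <- matrix(0, length(dxe), 8)
  for (g in seq_len(4)) {
    dN <- .shape_grad(.quad_gp[g, 1], .quad_gp[g, 2])
    dNx <- outer(2 / dxe, dN[1, ])   # nel x 4
    dNy <- outer(2 / dye, dN[2, ])
    F11 <- 1 + rowSums(ux * dNx); F12 <- rowSums(ux * dNy)
    F21 <- rowSums(uy * dNx);     F22 <- 1 + rowSums(uy * dNy)
    P <- pk1_ogden(F11, F12, F21, F22, mu, alpha, .sri_stab * kappa)
    for (i in 1:4) {
      floc[, 2 * i - 1] <- floc[, 2 * i - 1] +
        (P$P11 * dNx[, i] + P$P12 * dNy[, i]) * dV
      floc[, 2 * i] <- floc[, 2 * i] +
        (P$P21 * dNx[, i] + P$P22 * dNy[, i]) * dV
    }
  }
  # volumetric part, centroid: P_vol = kappa (J - 1) adj(F)^T
  dN <- .shape_grad(0, 0)
  dNx <- outer(2 / dxe, dN[1, ]); dNy <- outer(2 / dye, dN[2, ])
  F11 <- 1 + rowSums(ux * dNx); F12 <- rowSums(ux * dNy)
  F21 <- rowSums(uy * dNx);     F22 <- 1 + rowSums(uy * dNy)
  J <- F11 * F22 - F12 * F21
  c0 <- (1 - .sri_stab) * kappa * (J - 1) * (dxe * dye)
  for (i in 1:4) {
    floc[, 2 * i - 1] <- floc[, 2 * i - 1] +
      c0 * (F22 * dNx[, i] - F21 * dNy[, i])
    floc[, 2 * i] <- floc[, 2 * i] +
      c0 * (-F12 * dNx[, i] + F11 * dNy[, i])
  }
  floc
}

gather_local <- function(u, en) {
  list(ux = matrix(u[2 * en - 1], ncol = 4), uy = matrix(u[2 * en], ncol = 4))
}

element_dof_index <- function(en) {
  idx <- matrix(0L, nrow(en), 8)
  idx[, seq(1, 8, 2)] <- 2L * en - 1L
  idx[, seq(2, 8, 2)] <- 2L * en
  idx
}

# vectorized total-Lagrangian internal force over alive elements; `intact`
# is the per-element integrity factor (1 - damage): elements soften linearly
# once their shear strain passes the deletion threshold and are removed from
# `alive` when fully degraded, which regularizes the discrete removal
internal_force <- function(u, mesh, alive, mu, alpha, kappa, intact) {
  el <- which(alive)
  en <- mesh$elem[el, , drop = FALSE]
  g <- gather_local(u, en)
  floc <- local_element_forces(g$ux, g$uy, mesh$dx[el], mesh$dy[el],
                               mu, alpha, kappa) * intact[el]
  idx <- element_dof_index(en)
  f <- numeric(length(u))
  tm <- rowsum(as.vector(floc), as.vector(idx))
  f[as.integer(rownames(tm))] <- tm[, 1]
  f
}

# consistent tangent by vectorized finite differences of the local element
# force vectors (the element force depends only on its own nodal values, so
# one perturbation per local dof covers every element at once)
tangent_stiffness <- function(u, mesh, alive, mu, alpha, kappa, intact) {
  el <- which(alive)
  en <- mesh$elem[el, , drop = FALSE]
  g <- gather_local(u, en)
  dxe <- mesh$dx[el]; dye <- mesh$dy[el]
  f0 <- local_element_forces(g$ux, g$uy, dxe, dye, mu, alpha, kappa)
  delta <- 1e-6 * min(mesh$h)
  kvals <- matrix(0, length(el), 64)
  for (d in 1:8) {
    uxp <- g$ux; uyp <- g$uy
    node <- (d + 1) %/% 2
    if (d %% 2 == 1) uxp[, node] <- uxp[, node] + delta
    else uyp[, node] <- uyp[, node] + delta
    fd <- (local_element_forces(uxp, uyp, dxe, dye, mu, alpha, kappa) - f0) / delta
    kvals[, (d - 1) * 8 + (1:8)] <- fd * intact[el]
  }
  idx <- element_dof_index(en)
  ii <- idx[, rep(1:8, times = 8)]
  jj <- idx[, rep(1:8, each = 8)]
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                       x = as.vector(kvals),
                       dims = c(2 * mesh$nnode, 2 * mesh$nnode))
}

# vectorized first Piola-Kirchhoff stress of the one-term Ogden model
pk1_ogden <- function(F11, F12, F21, F22, mu, alpha, kappa) {
  C11 <- F11^2 + F21^2; C22 <- F12^2 + F22^2; C12 <- F11 * F12 + F21 * F22
  tr <- C11 + C22; dt <- pmax(C11 * C22 - C12^2, 1e-12)
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  l1s <- tr / 2 + disc; l2s <- pmax(tr / 2 - disc, 1e-12)
  l1 <- sqrt(l1s); l2 <- sqrt(l2s)
  J <- l1 * l2
  Jm <- J^(-1 / 3)
  a1 <- (Jm * l1)^alpha; a2 <- (Jm * l2)^alpha; a3 <- Jm^alpha
  mn <- (a1 + a2 + a3) / 3
  s1 <- ((2 * mu / alpha) * (a1 - mn) + kappa * J * (J - 1)) / l1s
  s2 <- ((2 * mu / alpha) * (a2 - mn) + kappa * J * (J - 1)) / l2s
  # principal directions of C
  e1x <- C12; e1y <- l1s - C11
  small <- abs(C12) < 1e-14 * pmax(abs(C11), abs(C22))
  e1x[small] <- ifelse(C11[small] >= C22[small], 1, 0)
  e1y[small] <- ifelse(C11[small] >= C22[small], 0, 1)
  nrm <- sqrt(e1x^2 + e1y^2); e1x <- e1x / nrm; e1y <- e1y / nrm
  e2x <- -e1y; e2y <- e1x
  S11 <- s1 * e1x^2 + s2 * e2x^2
  S22 <- s1 * e1y^2 + s2 * e2y^2
  S12 <- s1 * e1x * e1y + s2 * e2x * e2y
  list(P11 = F11 * S11 + F12 * S12, P12 = F11 * S12 + F12 * S22,
       P21 = F21 * S11 + F22 * S12, P22 = F21 * S12 + F22 * S22)
}

element_max_shear <- function(u, mesh, el) {
  en <- mesh$elem[el, , drop = FALSE]
  ux <- matrix(u[2 * en - 1], ncol = 4); uy <- matrix(u[2 * en], ncol = 4)
  dN <- .shape_grad(0, 0)
  dNx <- outer(2 / mesh$dx[el], dN[1, ]); dNy <- outer(2 / mesh$dy[el], dN[2, ])
  F11 <- 1 + rowSums(ux * dNx); F12 <- rowSums(ux * dNy)
  F21 <- rowSums(uy * dNx);     F22 <- 1 + rowSums(uy * dNy)
  C11 <- F11^2 + F21^2; C22 <- F12^2 + F22^2; C12 <- F11 * F12 + F21 * F22
  tr <- C11 + C22; dt <- pmax(C11 * C22 - C12^2, 1e-12)
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  e1 <- 0.5 * log(pmax(tr / 2 + disc, 1e-12))
  e2 <- 0.5 * log(pmax(tr / 2 - disc, 1e-12))
  list(shear = (pmax(e1, e2, 0) - pmin(e1, e2, 0)) / 2,
       J = (F11 * F22 - F12 * F21))
}

# penalty contact of candidate nodes against the rigid beveled punch; the
# normal force is a softplus-smoothed penalty kn * eps * log(1 + exp(g/eps))
# (C1 in the gap, which keeps the Newton active set from chattering),
# saturated smoothly at the tissue's penetration strength: the interface
# cannot transmit pressure beyond the limit pressure at which tissue fails
# under the advancing face (f_cap = strength x nodal tributary length)
punch_contact <- function(u, mesh, cand, apex_y, half_w, tanb, kn, mu_f, eps,
                          f_cap_front = Inf, f_cap_side = f_cap_front) {
  x <- mesh$X[cand, 1] + u[2 * cand - 1]
  y <- mesh$X[cand, 2] + u[2 * cand]
  ax <- abs(x)
  shoulder_y <- apex_y + half_w * tanb
  yface <- apex_y + ax * tanb
  near <- ax < half_w + 4 * eps & y > yface - 4 * eps & y < 1e-3
  out <- list(idx = integer(0))
  if (!any(near)) return(out)
  ci <- which(near)
  cosb <- 1 / sqrt(1 + tanb^2); sinb <- tanb * cosb
  pen_bot <- (y[ci] - yface[ci]) * cosb          # distance to wedge face
  pen_side <- half_w - ax[ci]
  side_ok <- y[ci] > shoulder_y
  use_side <- side_ok & (pen_side < pen_bot)
  sgn <- ifelse(x[ci] >= 0, 1, -1)
  nxv <- ifelse(use_side, sgn, sgn * sinb)
  nyv <- ifelse(use_side, 0, -cosb)
  pen <- ifelse(use_side, pen_side, pen_bot)
  z <- pen / eps
  fn <- kn * eps * ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(pmax(z, -30))))
  dfn <- kn / (1 + exp(-pmin(pmax(z, -30), 30)))  # d fn / d pen
  f_cap <- ifelse(use_side, f_cap_side, f_cap_front)
  cap_ok <- is.finite(f_cap)
  if (any(cap_ok)) {
    th <- tanh(fn / f_cap)
    dfn <- ifelse(cap_ok, dfn * (1 - th^2), dfn)
    fn <- ifelse(cap_ok, f_cap * th, fn)
  }
  keep <- fn > kn * eps * 1e-9
  if (!any(keep)) return(out)
  ci <- ci[keep]; fn <- fn[keep]; dfn <- dfn[keep]
  nxv <- nxv[keep]; nyv <- nyv[keep]; use_side <- use_side[keep]
  sgn <- sgn[keep]
  fx <- fn * nxv; fy <- fn * nyv
  # Coulomb friction: punch slides downward; drag on tissue along the face
  tx <- ifelse(use_side, 0, sgn * cosb)
  ty <- ifelse(use_side, 1, sinb)
  slip <- -(ty)                                   # punch velocity (0,-1) . t
  fx <- fx + mu_f * fn * slip * tx
  fy <- fy + mu_f * fn * slip * ty
  list(idx = cand[ci], fx = fx, fy = fy, fn = fn, dfn = dfn,
       nx = nxv, ny = nyv, side = use_side,
       fric_y = mu_f * fn * slip * ty)
}

#' Simulate quasi-static insertion of a coated probe into tissue
#'
#' Displacement-driven incremental solve of the reduced 2-D plane-strain
#' penetration model (see the package vignette for the model reduction and
#' its calibration). Returns the reaction-force profile and the insertion
#' force, defined as the peak force during penetration.
#'
#' @param assembly A [coated_assembly()]; the tip is the coating footprint
#'   when coated.
#' @param tissue A [tissue_model()] / [tissue_preset()] (default agarose, the
#'   phantom used for the reference force profile).
#' @param speed Insertion speed in m/s (recorded; the solve is quasi-static,
#'   default 0.1 mm/s).
#' @param mesh `"coarse"`, `"default"` or `"fine"`, or a list with elements
#'   `h` (element size, m), `domain_factor`, `depth` (max insertion, m).
#' @param max_depth Maximum apex travel in m (default 2.5 x tip width).
#' @param shear_measure Strain measure for deletion; only
#'   `"max_log_shear"` ((eps1 - eps3)/2 of logarithmic strain) is built in.
#' @param verbose Print increment diagnostics.
#' @return A `pf_force_profile`: `samples` (displacement_m, force_N,
#'   side_friction_N, n_deleted), `insertion_force` (N), `side_friction_force`
#'   (N at peak), `first_penetration` (m), `meta`.
#' @export
simulate_insertion <- function(assembly, tissue = tissue_preset("agarose"),
                               speed = 1e-4,
                               mesh = c("default", "coarse", "fine"),
                               max_depth = NULL,
                               shear_measure = "max_log_shear",
                               verbose = FALSE) {
  validate_assembly(assembly)
  ts <- tip_section(assembly)
  tip_w <- min(ts); w3d <- max(ts)
  theta <- tip_bevel(assembly)
  if (is.character(mesh)) {
    mesh <- match.arg(mesh)
    nfine <- c(coarse = 4, default = 5, fine = 8)[[mesh]]
    ctrl <- list(h = tip_w / nfine, domain_factor = 20)
  } else ctrl <- mesh
  if (is.null(ctrl$domain_factor)) ctrl$domain_factor <- 20
  if (ctrl$domain_factor < 10)
    pf_stop("pf_geometry_error", "tip wider than domain/10")
  if (is.null(max_depth)) max_depth <- ctrl$depth %||% (1.5 * tip_w)
  msh <- build_tissue_mesh(tip_w, max_depth, ctrl$h, ctrl$domain_factor)
  mu <- tissue$ogden_mu; alpha <- tissue$ogden_alpha
  gam_c <- tissue$deletion_threshold
  mu_f <- tissue$friction
  # interface limit pressure: the tissue's penetration strength evaluated at
  # the tip scale (the empirical sharpness law); the deletion threshold
  # enters through the resolved failure mechanics, not through the cap
  s_m <- tip_w^2 / (tip_w^2 + tissue$process_zone^2)
  sigma_cap <- tissue$penetration_strength * s_m * .pf_cal$fem_cap_shape
  # effective confinement modulus: the confined (oedometric) failure stress
  # E_conf * 2 gamma_c of the front-row elements is pinned just below the
  # interface limit pressure, so the face carves the tissue at near-cap load
  # (pinned at the default threshold 0.05 so the threshold sweep probes the
  # failure criterion, not the modulus; the margin keeps the limit pressure
  # below the onset of bulk failure so the front carries a sustained load
  # while the advancing face carves geometrically)
  kappa <- max(tissue$bulk_modulus, sigma_cap / (0.7 * 0.1))
  # front faces transmit up to the penetration strength through the crushed
  # process-zone layer; side walls only up to the tissue's own confined
  # failure stress (the carved channel relaxes to that level)
  kappa_phys <- tissue$small_strain_stiffness /
    (3 * (1 - 2 * tissue$poisson))
  sigma_wall <- (kappa_phys + 4 * mu / 3) * 2 * gam_c
  f_cap_front <- sigma_cap * msh$h
  f_cap_side <- min(sigma_cap, sigma_wall) * msh$h
  kn <- max(20 * (kappa + 4 * mu / 3), 100 * sigma_cap)  # Pa (per unit width)
  c_eps <- 0.05 * tip_w   # process-zone (debris layer) smoothing length
  tanb <- tan(theta * pi / 180)
  half_w <- tip_w / 2

  ndof <- 2 * msh$nnode
  u <- numeric(ndof)
  alive <- rep(TRUE, msh$nel)
  damage <- numeric(msh$nel)   # 0 intact .. 1 removed; never decreases
  topo_changed <- TRUE
  Kel <- NULL; free <- NULL; cand <- NULL
  refresh_topology <- function() {
    en <- msh$elem[alive, , drop = FALSE]
    an <- unique(as.vector(en))
    # contact candidates: nodes on the exposed surface of the alive mesh
    # (nodes of element edges used by exactly one alive element)
    e1 <- rbind(en[, c(1, 2)], en[, c(2, 3)], en[, c(3, 4)], en[, c(4, 1)])
    key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
    bnd <- e1[key %in% names(which(table(key) == 1)), , drop = FALSE]
    cand <<- setdiff(unique(as.vector(bnd)), msh$fixed_nodes)
    fd <- sort(c(2 * msh$fixed_nodes - 1, 2 * msh$fixed_nodes))
    orphan <- setdiff(seq_len(msh$nnode), an)
    fd <- sort(unique(c(fd, 2 * orphan - 1, 2 * orphan)))
    free <<- setdiff(seq_len(ndof), fd)
    topo_changed <<- FALSE
  }
  refresh_topology()

  ref_hist <- kn * msh$h * 1e-8   # running force scale for the tolerance
  residual_at <- function(u, apex_y) {
    cf <- punch_contact(u, msh, cand, apex_y, half_w, tanb, kn, mu_f, c_eps,
                        f_cap_front, f_cap_side)
    fc <- numeric(ndof)
    if (length(cf$idx)) {
      fc[2 * cf$idx - 1] <- cf$fx
      fc[2 * cf$idx] <- cf$fy
    }
    fint <- internal_force(u, msh, alive, mu, alpha, kappa, 1 - damage)
    R <- fc - fint
    ref <- max(abs(fc), abs(fint), kn * msh$h * 1e-8)
    ref_hist <<- max(ref_hist, ref)
    list(cf = cf, R = R, norm = max(abs(R[free])), ref = ref)
  }

  converged <- function(rs) rs$norm < 1e-4 * rs$ref || rs$norm < 1e-6 * ref_hist

  solve_at <- function(apex_y, u0) {
    u <- u0
    rs <- residual_at(u, apex_y)
    for (it in 1:80) {
      if (converged(rs)) return(list(u = u, cf = rs$cf, ok = TRUE))
      K <- tangent_stiffness(u, msh, alive, mu, alpha, kappa, 1 - damage)
      if (length(rs$cf$idx)) {
        cf <- rs$cf
        i1 <- 2 * cf$idx - 1; i2 <- 2 * cf$idx
        Kc <- Matrix::sparseMatrix(
          i = c(i1, i1, i2, i2), j = c(i1, i2, i1, i2),
          x = cf$dfn * c(cf$nx^2, cf$nx * cf$ny, cf$nx * cf$ny, cf$ny^2),
          dims = c(ndof, ndof))
        K <- K + Kc
      }
      Kf <- K[free, free]
      du <- tryCatch(
        as.numeric(Matrix::solve(Kf, rs$R[free])),
        error = function(e) NULL)
      if (is.null(du)) {
        # near-singular (debris mechanisms): retry with a small ridge
        ridge <- 1e-8 * max(abs(Kf@x))
        du <- tryCatch(
          as.numeric(Matrix::solve(Kf + ridge * Matrix::Diagonal(nrow(Kf)),
                                   rs$R[free])),
          error = function(e) NULL)
      }
      if (is.null(du)) break
      # backtracking line search on the residual norm (the small-strain
      # stiffness underestimates the locked Ogden response, so full modified
      # Newton steps can overshoot into a limit cycle)
      step <- 1; accepted <- FALSE
      for (ls in 1:6) {
        u_try <- u
        u_try[free] <- u[free] + step * du
        rs_try <- residual_at(u_try, apex_y)
        if (rs_try$norm < rs$norm * (1 - 1e-3 * step) ||
            (ls == 6 && rs_try$norm < 2 * rs$norm)) {
          u <- u_try; rs <- rs_try; accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
    }
    if (converged(rs)) list(u = u, cf = rs$cf, ok = TRUE)
    else list(u = u, cf = NULL, ok = FALSE)
  }

  # update damage and list elements to remove: an element starts to fail when
  # its maximum shear strain passes the deletion threshold, loses integrity
  # linearly until 1.5x the threshold, and is then removed. Compaction beyond
  # a volumetric strain of 4x the threshold fails the element the same way
  # (material crushed under the advancing face cannot resist indefinitely).
  # Crushed (near-inverted) or dangling elements are removed outright.
  deletion_set <- function(u, apex_y) {
    el <- which(alive)
    st <- element_max_shear(u, msh, el)
    eqv <- pmax(st$shear, abs(log(pmax(st$J, 1e-6))) / 4)
    dm <- pmin(pmax((eqv - gam_c) / (2 * gam_c), 0), 1)
    damage[el] <<- pmax(damage[el], dm)
    cx <- rowMeans(matrix(msh$X[msh$elem[el, ], 1], ncol = 4)) +
      rowMeans(matrix(u[2 * msh$elem[el, ] - 1], ncol = 4))
    cy <- rowMeans(matrix(msh$X[msh$elem[el, ], 2], ncol = 4)) +
      rowMeans(matrix(u[2 * msh$elem[el, ]], ncol = 4))
    swallowed <- abs(cx) < half_w &
      cy > apex_y + abs(cx) * tanb + 0.6 * msh$h
    # dangling debris: elements sharing at most one node with the rest of
    # the alive mesh form mechanisms and are removed with the failed set
    en <- msh$elem[el, , drop = FALSE]
    usage <- tabulate(en, nbins = msh$nnode)
    shared <- matrix(usage[en] > 1, ncol = 4)
    dangling <- rowSums(shared) <= 1
    kill <- el[damage[el] >= 1 | swallowed | st$J < 0.15 | dangling]
    # quasi-statics removes failures sequentially: drop only the worst few,
    # re-equilibrate, and let the cascade loop decide whether others follow
    if (length(kill) > 3) {
      ord <- order(damage[kill], st$shear[match(kill, el)], decreasing = TRUE)
      keep_dangling <- kill[dangling[match(kill, el)]]
      kill <- unique(c(kill[ord[1:3]], keep_dangling))
    }
    list(kill = kill, el = el, shear = st$shear)
  }

  d_step <- msh$h / 2
  depths <- seq(d_step, max_depth, by = d_step)
  prof <- vector("list", length(depths))
  first_pen <- NA_real_
  n_del_total <- 0
  for (k in seq_along(depths)) {
    if (topo_changed) refresh_topology()
    apex_y <- -depths[k]
    sol <- solve_at(apex_y, u)
    if (!sol$ok) {
      # adaptive substepping: approach the target depth in quarters
      ok <- TRUE
      for (dq in seq(depths[k] - 0.75 * d_step, depths[k], by = 0.25 * d_step)) {
        sol <- solve_at(-dq, u)
        if (!sol$ok) { ok <- FALSE; break }
        u <- sol$u
      }
      # a stalled increment is almost always a failure front that cannot
      # advance without removing its most-strained element; do so and retry
      tries <- 0
      while (!ok && tries < 6) {
        ds <- deletion_set(u, apex_y)
        if (!length(ds$el)) break
        worst <- ds$el[which.max(ds$shear)]
        alive[unique(c(ds$kill, worst))] <- FALSE
        n_del_total <- n_del_total + length(unique(c(ds$kill, worst)))
        if (is.na(first_pen)) first_pen <- depths[k]
        refresh_topology()
        sol <- solve_at(apex_y, u)
        ok <- sol$ok
        tries <- tries + 1
      }
      if (!ok)
        pf_stop("pf_solver_error",
                "Newton failed at depth %.3g um after substepping",
                depths[k] * 1e6)
    }
    u <- sol$u
    cf <- sol$cf
    Fins <- if (length(cf$idx)) -sum(cf$fy) * w3d else 0
    Fside <- if (length(cf$idx)) sum(abs(cf$fric_y[cf$side])) * w3d else 0
    # deletion pass(es): remove failed elements, re-equilibrate at the same
    # depth, and let deletions cascade before the next increment
    n_before <- n_del_total
    rounds <- 0
    repeat {
      ds <- deletion_set(u, apex_y)
      if (!length(ds$kill) || rounds >= 2) break
      alive[ds$kill] <- FALSE
      topo_changed <- TRUE
      n_del_total <- n_del_total + length(ds$kill)
      if (is.na(first_pen)) first_pen <- depths[k]
      refresh_topology()
      sol2 <- solve_at(apex_y, u)
      if (!sol2$ok) break
      u <- sol2$u
      rounds <- rounds + 1
    }
    n_killed <- n_del_total - n_before
    prof[[k]] <- c(depths[k], Fins, Fside, n_killed)
    if (verbose)
      message(sprintf("depth %6.1f um  F = %8.4f mN  Fside = %8.5f mN  del %d",
                      depths[k] * 1e6, Fins * 1e3, Fside * 1e3, n_killed))
  }
  sm <- do.call(rbind, prof)
  samples <- data.frame(displacement_m = sm[, 1], force_N = sm[, 2],
                        side_friction_N = sm[, 3], n_deleted = sm[, 4])
  ipk <- which.max(samples$force_N)
  structure(list(samples = samples,
                 insertion_force = samples$force_N[ipk],
                 side_friction_force = max(samples$side_friction_N),
                 first_penetration = first_pen,
                 meta = list(h = msh$h, n_elements = msh$nel,
                             domain_factor = ctrl$domain_factor,
                             deleted = n_del_total, speed = speed,
                             shear_measure = shear_measure,
                             tissue = tissue$name,
                             threshold = gam_c, friction = mu_f,
                             out_of_plane_width = w3d)),
            class = "pf_force_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pf_force_profile <- function(x, ...) {
  cat(sprintf("insertion force = %.4g mN (peak), side friction = %.4g mN, %d elements deleted\n",
              mN(x$insertion_force), mN(x$side_friction_force), x$meta$deleted))
  invisible(x)
}
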