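# One-term compressible Ogden constitutive model.
# Strain energy (principal stretches lam_i, J = lam1*lam2*lam3,
# lbar_i = J^(-1/3) lam_i):
#   W = 2 mu / alpha^2 * (lbar1^alpha + lbar2^alpha + lbar3^alpha - 3)
#       + kappa/2 * (J - 1)^2
# Small-strain shear modulus is mu; small-strain bulk modulus is kappa.

ogden_principal_cauchy <- function(lam, mu, alpha, kappa) {
  if (any(lam <= 0)) pf_stop("pf_constitutive_error",
                             "principal stretches must be > 0")
  J <- prod(lam)
  lb <- J^(-1 / 3) * lam
  lba <- lb^alpha
  tau_dev <- (2 * mu / alpha) * (lba - mean(lba))
  tau_vol <- kappa * J * (J - 1)
  (tau_dev + tau_vol) / J
}

#' Cauchy stress of the one-term compressible Ogden model
#'
#' @param F Deformation gradient: a 2x2 matrix (plane strain, out-of-plane
#'   stretch 1) or a 3x3 matrix.
#' @param mu Ogden shear parameter (Pa); equals the small-strain shear modulus.
#' @param alpha Ogden exponent.
#' @param kappa Bulk modulus (Pa).
#' @return Symmetric 3x3 Cauchy stress (Pa).
#' @examples
#' ogden_stress(diag(3), 1e3, -4.7, 1e5)  # zero at the reference state
#' @export
ogden_stress <- function(F, mu, alpha, kappa) {
  if (is.matrix(F) && all(dim(F) == 2)) {
    F3 <- diag(3); F3[1:2, 1:2] <- F
  } else if (is.matrix(F) && all(dim(F) == 3)) F3 <- F
  else pf_stop("pf_constitutive_error", "F must be 2x2 or 3x3")
  b <- F3 %*% t(F3)
  eb <- eigen(b, symmetric = TRUE)
  lam2 <- pmax(eb$values, .Machine$double.eps)
  sig_p <- ogden_principal_cauchy(sqrt(lam2), mu, alpha, kappa)
  s <- eb$vectors %*% diag(sig_p) %*% t(eb$vectors)
  (s + t(s)) / 2
}

#' Maximum shear strain of a deformation state
#'
#' Half the difference between the extreme principal logarithmic (Hencky)
#' strains, `(eps_1 - eps_3) / 2` — the scalar against which the element
#' deletion threshold is tested. For plane-strain states the zero out-of-plane
#' strain participates as a principal value.
#'
#' @param F Deformation gradient (2x2 plane strain or 3x3).
#' @return Non-negative scalar.
#' @examples
#' max_shear_strain(diag(2))  # 0
#' @export
#' @rdname max_shear_strain
max_shear_strain <- function(F) {
  if (is.matrix(F) && all(dim(F) == 2)) {
    C <- t(F) %*% F
    lam2 <- c(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 1)
  } else {
    C <- t(F) %*% F
    lam2 <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  }
  eps <- 0.5 * log(pmax(lam2, .Machine$double.eps))
  (max(eps) - min(eps)) / 2
}
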