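# shared builders for the test suite

ref_assembly <- function(bevel = 45) {
  coated_assembly(probe_spec(20, 5, 3500, "su8"),
                  coating_spec(75, 100, 4000, bevel_angle = bevel))
}

blade_assembly <- function() coated_assembly(probe_spec(40, 10, 3500, "su8"))

# shooting-method oracle for the critical load of a (possibly stepped)
# pinned-pinned column: integrates w' = th, th' = M/EI(x), M' = V,
# V' = -P th' with RK4 and finds P where the end conditions vanish
shooting_critical_load <- function(EI_fun, L, n = 2000) {
  det_end <- function(P) {
    h <- L / n
    rhs <- function(x, y) {
      dth <- y[3] / EI_fun(x)
      c(y[2], dth, y[4], -P * dth)
    }
    ends <- sapply(list(c(0, 1, 0, 0), c(0, 0, 0, 1)), function(y0) {
      y <- y0; x <- 0
      for (i in seq_len(n)) {
        k1 <- rhs(x, y); k2 <- rhs(x + h / 2, y + h / 2 * k1)
        k3 <- rhs(x + h / 2, y + h / 2 * k2); k4 <- rhs(x + h, y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        x <- x + h
      }
      c(y[1], y[3])   # w(L), M(L)
    })
    det(ends)
  }
  # bracket the first root above a small positive load
  EI_min <- min(sapply(seq(0, L, length.out = 50), EI_fun))
  P_lo <- 0.2 * pi^2 * EI_min / L^2
  P_hi <- P_lo * 1.2
  while (sign(det_end(P_hi)) == sign(det_end(P_lo)) && P_hi < 1e4 * P_lo)
    P_hi <- P_hi * 1.2
  uniroot(det_end, c(P_lo, P_hi), tol = 1e-10 * P_hi)$root
}

# numeric Ogden stress oracle: Cauchy stress from central differences of the
# strain-energy density with respect to the deformation gradient
ogden_energy <- function(F3, mu, alpha, kappa) {
  lam <- sqrt(pmax(eigen(t(F3) %*% F3, symmetric = TRUE,
                         only.values = TRUE)$values, 1e-300))
  J <- prod(lam)
  lb <- J^(-1 / 3) * lam
  2 * mu / alpha^2 * (sum(lb^alpha) - 3) + kappa / 2 * (J - 1)^2
}

ogden_stress_oracle <- function(F3, mu, alpha, kappa) {
  P <- matrix(0, 3, 3)
  hstep <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    Fp <- F3; Fm <- F3
    Fp[i, j] <- Fp[i, j] + hstep
    Fm[i, j] <- Fm[i, j] - hstep
    P[i, j] <- (ogden_energy(Fp, mu, alpha, kappa) -
                ogden_energy(Fm, mu, alpha, kappa)) / (2 * hstep)
  }
  s <- P %*% t(F3) / det(F3)
  (s + t(s)) / 2
}

# synthetic cohort generator: binomial outcomes from a true logistic
synth_cohorts <- function(k, sf50, sf = seq(0.4, 3.2, length.out = 12),
                          n = 50) {
  data.frame(safety_factor = sf,
             n_pass = rbinom(length(sf), n, plogis(k * (sf - sf50))),
             n_total = n)
}
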