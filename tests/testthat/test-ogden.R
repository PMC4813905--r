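test_that("reference state is stress free and invalid stretches error", {
  s <- ogden_stress(diag(3), 1e3, -4.7, 1e5)
  expect_equal(max(abs(s)), 0, tolerance = 1e-12)
  expect_error(ogden_stress(matrix(1, 2, 3), 1e3, -4.7, 1e5),
               class = "pf_constitutive_error")
  expect_error(probeflex:::ogden_principal_cauchy(c(1, -0.1, 1), 1e3, -4.7, 1e5),
               class = "pf_constitutive_error")
})

test_that("Ogden stress matches the energy-differentiation oracle", {
  mu <- 1e3; alpha <- -4.7; kappa <- 5e4
  states <- list(diag(c(1.1, 1, 1)),
                 diag(c(0.95, 1.08, 0.99)),
                 matrix(c(1, 0.05, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  for (F3 in states) {
    s_imp <- ogden_stress(F3, mu, alpha, kappa)
    s_ref <- ogden_stress_oracle(F3, mu, alpha, kappa)
    expect_lt(max(abs(s_imp - s_ref)) / max(abs(s_ref)), 1e-6)
  }
})

test_that("small-strain shear response recovers the shear modulus", {
  mu <- 1e3; gam <- 1e-4
  F2 <- matrix(c(1, gam, 0, 1), 2, 2, byrow = TRUE)
  s <- ogden_stress(F2, mu, -4.7, 5e4)
  expect_equal(s[1, 2] / gam, mu, tolerance = 1e-2)
})

test_that("maximum shear strain matches tensor algebra and an eigen oracle", {
  expect_equal(max_shear_strain(diag(2)), 0)
  gam <- 1e-4
  F2 <- matrix(c(1, gam, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(max_shear_strain(F2), gam / 2, tolerance = 1e-3)
  set.seed(4)
  for (i in 1:20) {
    F3 <- diag(3) + matrix(rnorm(9, sd = 5e-3), 3, 3)
    eps <- 0.5 * log(eigen(t(F3) %*% F3, symmetric = TRUE,
                           only.values = TRUE)$values)
    expect_equal(max_shear_strain(F3), (max(eps) - min(eps)) / 2,
                 tolerance = 1e-10)
  }
})

test_that("confined-compression stress increases with the failure threshold", {
  tis <- tissue_preset("agarose")
  s <- sapply(c(0.01, 0.05, 0.25), function(th) ogden_confined_stress(tis, th))
  expect_true(all(s > 0))
  expect_true(all(diff(s) > 0))
})

test_that("tissue model enforces its parameter ranges", {
  expect_error(tissue_model(friction = 0.7), class = "pf_domain_error")
  expect_error(tissue_model(deletion_threshold = 0.001), class = "pf_domain_error")
  t1 <- tissue_model(small_strain_stiffness = 2.5e3, poisson = 0.49)
  expect_equal(t1$ogden_mu, 2.5e3 / (2 * 1.49))
  expect_equal(t1$bulk_modulus, 2.5e3 / (3 * 0.02))
})
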