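# penetration solver tests run at the coarse mesh unless the property needs
# the default discretization; each run is a fraction of a second to a few
# seconds

test_that("default insertion run produces a physical force profile", {
  prof <- simulate_insertion(ref_assembly(), tissue_preset("agarose"))
  s <- prof$samples
  expect_true(all(s$force_N >= 0))
  expect_gt(prof$insertion_force, 0)
  expect_false(is.na(prof$first_penetration))
  # peak is reached at or after first penetration of the surface
  ipk <- which.max(s$force_N)
  expect_gte(s$displacement_m[ipk], prof$first_penetration)
  # characteristic shape: after the first near-peak sample the force drops
  first_hi <- which(s$force_N >= 0.9 * max(s$force_N))[1]
  expect_lt(min(s$force_N[first_hi:nrow(s)]), 0.9 * max(s$force_N))
  # deletion happened and the count only accumulates
  expect_gt(prof$meta$deleted, 0)
  expect_true(all(s$n_deleted >= 0))
})

test_that("side friction is well below the insertion force at defaults", {
  prof <- simulate_insertion(ref_assembly(), tissue_preset("agarose"))
  expect_lt(prof$side_friction_force, prof$insertion_force / 10)
})

test_that("frictionless tissue transmits no side drag; friction raises it", {
  p0 <- simulate_insertion(ref_assembly(), tissue_preset("agarose", friction = 0),
                           mesh = "coarse")
  p5 <- simulate_insertion(ref_assembly(), tissue_preset("agarose", friction = 0.5),
                           mesh = "coarse")
  expect_equal(p0$side_friction_force, 0)
  expect_gt(p5$side_friction_force, 0)
})

test_that("insertion force scales with the tissue penetration strength", {
  tis <- tissue_preset("agarose")
  weak <- tis; weak$penetration_strength <- tis$penetration_strength / 10
  F1 <- simulate_insertion(ref_assembly(), tis, mesh = "coarse")$insertion_force
  F2 <- simulate_insertion(ref_assembly(), weak, mesh = "coarse")$insertion_force
  expect_lt(F2, F1 / 3)
})

test_that("insertion force is monotone in the deletion threshold", {
  Fs <- sapply(c(0.01, 0.05, 0.25), function(th)
    simulate_insertion(ref_assembly(),
                       tissue_preset("agarose", deletion_threshold = th)
                       )$insertion_force)
  expect_true(all(diff(Fs) >= 0))
})

test_that("geometry guards reject an undersized domain", {
  expect_error(
    simulate_insertion(ref_assembly(), tissue_preset("agarose"),
                       mesh = list(h = 15e-6, domain_factor = 5)),
    class = "pf_geometry_error")
})

test_that("sensitivity sweep reports zero change at the default value", {
  out <- sensitivity_sweep(ref_assembly(), tissue_preset("agarose"),
                           parameter = "deletion_threshold", values = 0.05,
                           backend = "fem", mesh = "coarse")
  expect_equal(out$pct_change, 0, tolerance = 1e-10)
  out2 <- sensitivity_sweep(ref_assembly(), tissue_preset("agarose"),
                            parameter = "friction", values = c(0.3),
                            backend = "surrogate")
  expect_equal(out2$pct_change, 0, tolerance = 1e-10)
})

test_that("surrogate agrees with the solver on the calibration grid", {
  cal <- calibrate_surrogate(mesh = "coarse")
  expect_true(all(abs(cal$residuals) < 0.25))
})
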