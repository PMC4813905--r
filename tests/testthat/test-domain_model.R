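test_that("material library carries the probe/coating constants in SI units", {
  lib <- material_library()
  expect_named(lib, c("copper", "su8", "parylene_c", "coating"))
  expect_equal(lib$parylene_c$modulus, 5.6e6)
  expect_equal(lib$copper$modulus, 110e9)
  expect_equal(lib$su8$modulus, 2.4e9)
  expect_equal(lib$coating$modulus, 1.9e9)
  expect_equal(lib$coating$poisson, 0.42)
  expect_equal(lib$copper$poisson, 0.36)
  expect_true(all(sapply(lib, `[[`, "density") > 1000))
})

test_that("material invariants are enforced and extras can be registered", {
  expect_error(material("x", -1, 1000, 0.3), class = "pf_domain_error")
  expect_error(material("x", 1e9, 1000, 0.5), class = "pf_domain_error")
  lib <- material_library(extra = list(peg = material("peg", 2e9, 1100, 0.4)))
  expect_equal(lib$peg$modulus, 2e9)
})

test_that("assembly validation enforces enclosure and positive dimensions", {
  ok <- coated_assembly(probe_spec(20, 5, 3500, "parylene_c"),
                        coating_spec(50, 100, 4000))
  expect_s3_class(ok, "pf_assembly")
  expect_error(
    coated_assembly(probe_spec(320, 20, 3500, "su8"), coating_spec(50, 50, 4000)),
    class = "pf_geometry_error")
  expect_error(probe_spec(0, 5, 3500, "su8"), class = "pf_domain_error")
  expect_error(probe_spec(20, 5, 10, "su8"), class = "pf_domain_error")
})

test_that("micrometre interface converts to SI and back exactly", {
  p <- probe_spec(320, 5, 3500, "su8")
  expect_identical(m_to_um(p$width), 320)
  expect_identical(m_to_um(p$thickness), 5)
  expect_equal(m_to_um(um_to_m(123.456)), 123.456, tolerance = 1e-14)
})

test_that("cohort fixtures reproduce every printed success rate from counts", {
  chick <- load_cohort_fixtures("chick")
  rat <- load_cohort_fixtures("rat")
  expect_length(chick, 15)
  expect_length(rat, 7)
  expect_equal(chick[[10]]$n_pass / chick[[10]]$n_total, 0.5)    # 4/8
  expect_equal(round(100 * rat[[1]]$success_rate, 1), 54.5)      # 6/11
  expect_equal(rat[[3]]$n_pass, 0)                               # 0/8
  for (co in c(chick, rat)) {
    expect_true(co$n_pass >= 0 && co$n_pass <= co$n_total)
    expect_equal(co$success_rate, co$n_pass / co$n_total)
  }
})

test_that("oversized-probe cohorts are interpreted as per-side coating layers", {
  chick <- load_cohort_fixtures("chick")
  co3 <- chick[[3]]  # SU-8 320 x 20 probe listed with a 50 x 50 coating
  expect_true(co3$assembly$coating$thickness >= co3$assembly$probe$thickness)
  expect_true(co3$assembly$coating$width >= co3$assembly$probe$width)
  expect_equal(m_to_um(co3$assembly$coating$thickness), 20 + 2 * 50)
})

test_that("coating-only shank cohort substitutes a negligible probe", {
  rat <- load_cohort_fixtures("rat")
  expect_lt(rat[[7]]$assembly$probe$material$modulus, 1e6)
})
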