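test_that("Euler critical force follows the closed form and its scalings", {
  expect_equal(euler_critical_force(1, 1, "pinned_pinned"), pi^2)
  s <- composite_section(coated_assembly(probe_spec(320, 20, 3500, "su8")))
  expect_equal(s$flexural_rigidity, 2.4e9 * 320e-6 * (20e-6)^3 / 12)
  F1 <- euler_critical_force(s, 3500e-6)
  F2 <- euler_critical_force(s, 3500e-6 / 2)
  expect_equal(F2 / F1, 4)
  # effective-length ordering: fixed_free weakest, fixed_fixed strongest
  Fs <- sapply(c("fixed_free", "pinned_pinned", "fixed_pinned", "fixed_fixed"),
               function(bc) euler_critical_force(s, 3500e-6, bc))
  expect_true(all(diff(Fs) > 0))
})

test_that("composite section: soft probe inside a stiff square coating", {
  asm <- coated_assembly(probe_spec(20, 5, 3500, "parylene_c"),
                         coating_spec(100, 100, 4000))
  EI <- composite_section(asm)$flexural_rigidity
  EI_full <- 1.9e9 * (100e-6)^4 / 12
  expect_equal(EI, EI_full, tolerance = 1e-3)
  # a vanishing layer recovers the bare-probe rigidity
  p <- probe_spec(20, 5, 3500, "su8")
  EI0 <- composite_section(coated_assembly(p))$flexural_rigidity
  EI_eps <- composite_section(coat_probe(p, layer = 1e-6))$flexural_rigidity
  expect_equal(EI_eps, EI0, tolerance = 1e-4)
})

test_that("FE buckling matches Euler on uniform columns and converges", {
  asm <- coated_assembly(probe_spec(320, 20, 3500, "su8"))
  Fe <- euler_critical_force(composite_section(asm), 3500e-6, "pinned_pinned")
  err <- sapply(c(10, 50), function(n)
    abs(fe_buckling(asm, bc = "pinned_pinned", n_elements = n)$critical_force - Fe) / Fe)
  expect_lt(err[2], 1e-3)
  expect_lt(err[2], err[1])   # monotone refinement
  # copper wire, fixed-pinned: closed form vs eigen solver
  wire <- coated_assembly(probe_spec(length = 10e3, material = "copper",
                                     shape = "circular", diameter = 320))
  Fw <- euler_critical_force(composite_section(wire), 10e-3, "fixed_pinned")
  Ff <- fe_buckling(wire, bc = "fixed_pinned", n_elements = 100)$critical_force
  expect_equal(Ff, Fw, tolerance = 2e-3)
  expect_equal(composite_section(wire)$flexural_rigidity,
               110e9 * pi * (320e-6)^4 / 64)
})

test_that("stepped columns match a shooting-method oracle", {
  EI1 <- 1e-9; EI2 <- 4e-9; L <- 4e-3
  EI_fun <- function(x) ifelse(x < 0.9 * L, EI2, EI1)  # coated over 90%
  P_ref <- shooting_critical_load(EI_fun, L)
  n <- 200
  xe <- (seq_len(n) - 0.5) / n * L
  fe <- fe_buckling(EI = ifelse(xe < 0.9 * L, EI2, EI1), length = L,
                    bc = "pinned_pinned")
  expect_equal(fe$critical_force, P_ref, tolerance = 1e-2)
})

test_that("coated assembly via FE equals the composite closed form", {
  asm <- coated_assembly(probe_spec(20, 5, 3500, "parylene_c"),
                         coating_spec(100, 100, 4000))
  Fe <- euler_critical_force(composite_section(asm), 4000e-6, "fixed_pinned")
  Ff <- fe_buckling(asm, n_elements = 100)$critical_force
  expect_equal(Ff, Fe, tolerance = 1e-2)
})

test_that("mode shape honours the boundary conditions", {
  asm <- coated_assembly(probe_spec(320, 20, 3500, "su8"))
  fb <- fe_buckling(asm, bc = "fixed_pinned", n_elements = 60)
  w <- fb$mode_shape$w
  expect_equal(w[1], 0)
  expect_equal(w[length(w)], 0)
  expect_equal(max(abs(w)), 1)
})

test_that("critical force rises with coating thickness and falls with length", {
  p <- probe_spec(20, 5, 3500, "parylene_c")
  Fb <- sapply(c(30, 60, 120), function(tc)
    buckling_force(coated_assembly(p, coating_spec(tc, 100, 4000))))
  expect_true(all(diff(Fb) > 0))
  Fl <- sapply(c(2000, 4000, 8000), function(L)
    buckling_force(coated_assembly(probe_spec(20, 5, L - 500, "parylene_c"),
                                   coating_spec(75, 100, L))))
  expect_true(all(diff(Fl) < 0))
})
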