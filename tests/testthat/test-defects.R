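test_that("defect descriptors enforce their ranges", {
  expect_error(void_defect(0.01), class = "pf_domain_error")
  expect_error(void_defect(1.5), class = "pf_domain_error")
  asm <- ref_assembly()
  expect_error(apply_defect(asm, void_defect(0.2, "side",
                                             axial_position_um = 9000)),
               class = "pf_geometry_error")
  expect_error(apply_defect(blade_assembly(), void_defect(0.2)),
               class = "pf_geometry_error")
})

test_that("a tiny side void barely changes the safety factor", {
  asm <- ref_assembly()
  tis <- tissue_preset("brain")
  base <- predict_insertion(asm, tis)
  dd <- apply_defect(asm, void_defect(0.05, "side"))
  def <- predict_defective(dd, tis)
  expect_lt(abs(def$safety_factor / base$safety_factor - 1), 0.01)
})

test_that("voided section rigidity matches a grid-integration oracle", {
  asm <- ref_assembly()   # coating 75 x 100 um
  cc <- asm$coating
  for (frac in c(0.3, 0.6)) {   # fully interior and clipped-circle branches
    r <- frac * cc$thickness
    EI <- probeflex:::voided_section_EI(asm, r)
    # independent fine-grid integration of the voided rectangle about the
    # weak axis (thickness direction), circle centred on the centroid
    n <- 1200
    ys <- (seq_len(n) - 0.5) / n * cc$thickness - cc$thickness / 2
    xs <- (seq_len(n) - 0.5) / n * cc$width - cc$width / 2
    dA <- (cc$thickness / n) * (cc$width / n)
    yy <- matrix(ys, n, n); xx <- matrix(xs, n, n, byrow = TRUE)
    keep <- (xx^2 + yy^2) > r^2
    I_ref <- sum(yy[keep]^2) * dA
    EI_ref <- cc$material$modulus * I_ref +
      composite_section(asm)$flexural_rigidity -
      cc$material$modulus * probeflex:::rect_I(cc$width, cc$thickness)
    expect_equal(EI, EI_ref, tolerance = 5e-3)
  }
})

test_that("tip voids raise the insertion force; mid-shank side voids do not", {
  asm <- ref_assembly()
  tis <- tissue_preset("brain")
  F0 <- surrogate_insertion_force(asm, tis)
  F_tip <- probeflex:::defective_insertion_force(
    apply_defect(asm, void_defect(0.3, "tip")), tis)
  F_side <- probeflex:::defective_insertion_force(
    apply_defect(asm, void_defect(0.3, "side")), tis)
  expect_gt(F_tip, F0)
  expect_equal(F_side, F0)
})

test_that("safety-factor loss grows with void size and is tip-dominated", {
  tbl <- defect_sensitivity(coating_thicknesses_um = 100,
                            fractions = c(0.1, 0.25, 0.5),
                            sites = c("tip", "side"))
  for (site in c("tip", "side")) {
    d <- tbl[tbl$site == site, ]
    expect_true(all(diff(abs(d$pct_dSF)) >= -1e-8))
  }
  for (f in unique(tbl$radius_fraction)) {
    expect_gte(abs(tbl$pct_dSF[tbl$site == "tip" & tbl$radius_fraction == f]),
               abs(tbl$pct_dSF[tbl$site == "side" & tbl$radius_fraction == f]))
  }
})

test_that("a fixed 50 um void hurts thin coatings the most", {
  tbl <- defect_sensitivity(void_diameter_um = 50, sites = "tip")
  expect_true(all(diff(tbl$pct_dSF) > 0))   # decreases are worst at 50 um
  expect_lt(min(tbl$pct_dSF), -5)
})
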