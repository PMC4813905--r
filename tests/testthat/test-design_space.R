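test_that("design space carries the modeled ranges with increasing grids", {
  ds <- design_space(n_grid = 8)
  expect_equal(ds$parameters$coating_thickness$range, c(0, 200))
  expect_equal(ds$parameters$probe_length$range, c(0.01, 10))
  expect_equal(ds$parameters$brain_stiffness$range, c(0.5, 5))
  for (p in ds$parameters) expect_true(all(diff(p$grid) > 0))
})

test_that("a one-point sweep equals a direct mechanics call", {
  ds <- design_space(n_grid = 2)
  tbl <- sweep_design(ds, free = "bevel_angle",
                      fixed = list(coating_thickness = 50))
  dp <- probeflex:::design_point(tbl[1, names(ds$parameters)])
  expect_equal(tbl$F_buckle_mN[1], 1e3 * buckling_force(dp$assembly))
  expect_equal(tbl$F_insert_mN[1],
               1e3 * surrogate_insertion_force(dp$assembly, dp$tissue))
})

test_that("safety factor is monotone in coating thickness and falls with length", {
  ds <- design_space(n_grid = 8)
  tc <- sweep_design(ds, free = "coating_thickness")
  expect_true(all(diff(tc$safety_factor) >= 0))
  tl <- sweep_design(ds, free = "probe_length")
  expect_true(all(diff(tl$safety_factor) < 0))
  # 1/L^2 scaling of the buckling side at fixed coating (insertion force is
  # length independent): SF ratio equals the squared column-length ratio
  L <- tl$probe_length * 1e3 + 500   # column = coating length, um
  expect_equal(tl$safety_factor[2] / tl$safety_factor[5],
               (L[5] / L[2])^2, tolerance = 1e-6)
})

test_that("probability maps stay in [0,1] and interpolate missing cells", {
  fit <- fit_logistic(cohort_safety_factors())
  ds <- design_space(n_grid = 10)
  tbl <- sweep_design(ds, free = c("coating_thickness", "probe_length"))
  pm <- probability_map(tbl, fit, c("coating_thickness", "probe_length"))
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  expect_equal(dim(pm$values), c(10, 10))
  # knock out interior cells; bilinear fill stays close to the full map
  set.seed(2)
  tbl2 <- tbl
  tbl2$ok[sample(nrow(tbl2), 25)] <- FALSE
  pm2 <- probability_map(tbl2, fit, c("coating_thickness", "probe_length"))
  expect_true(any(pm2$interpolated))
  expect_lt(mean(abs(pm2$values - pm$values)), 0.05)
  # excessive gaps are refused
  tbl3 <- tbl; tbl3$ok[1:60] <- FALSE
  expect_error(probability_map(tbl3, fit, c("coating_thickness", "probe_length")),
               class = "pf_coverage_error")
})

test_that("map orientation: long probes with thin coatings fail", {
  fit <- fit_logistic(cohort_safety_factors())
  tbl <- sweep_design(design_space(n_grid = 10),
                      free = c("coating_thickness", "probe_length"))
  pm <- probability_map(tbl, fit, c("coating_thickness", "probe_length"))
  # rho1 = coating thickness (rows), rho2 = length (cols): thin-coating,
  # long-probe corner fails; thick-coating, short-probe corner succeeds
  expect_lt(pm$values[1, 10], 0.2)
  expect_gt(pm$values[10, 1], 0.95)
})

test_that("map statistics: conventions, degenerate maps and known rows", {
  g <- seq(-3, 3, length.out = 41)
  prof <- dnorm(g)
  pmap <- structure(list(param1 = list(name = "a", grid = g),
                         param2 = list(name = "b", grid = 1:3),
                         values = matrix(rep(prof, 3), ncol = 3),
                         interpolated = matrix(FALSE, 41, 3),
                         provenance = list()), class = "pf_probability_map")
  st <- map_statistics(pmap, convention = "density")
  # brute-force moment oracle on the discretized gaussian profile
  w <- prof / sum(prof)
  mu <- sum(w * g); v <- sum(w * (g - mu)^2)
  expect_equal(st$kurtosis, sum(w * (g - mu)^4) / v^2, tolerance = 1e-10)
  expect_equal(st$kurtosis, 3, tolerance = 0.1)
  expect_equal(st$skewness, 0, tolerance = 1e-8)
  # values convention on a mostly-successful row reproduces binary moments
  pmap$values <- matrix(rep(c(rep(0, 4), rep(1, 37)), 3), ncol = 3)
  st2 <- map_statistics(pmap, convention = "values")
  p <- mean(c(rep(0, 4), rep(1, 37)))
  m <- c(rep(0, 4), rep(1, 37)) - p
  expect_equal(st2$kurtosis, mean(m^4) / mean(m^2)^2, tolerance = 1e-10)
  expect_lt(st2$skewness, -2)   # left tail: few failures among successes
  # constant map is degenerate
  pmap$values <- matrix(0.7, 41, 3)
  expect_error(map_statistics(pmap), class = "pf_degenerate_map")
})

test_that("regression recovers a known linear truth and flags collinearity", {
  set.seed(9)
  tbl <- sweep_design(design_space(), sample_n = 150, seed = 3)
  x1 <- tbl$coating_thickness; x2 <- tbl$probe_length
  tbl$safety_factor <- 2 * x1 - 3 * x2 + rnorm(nrow(tbl), sd = 0.5)
  rg <- regress_safety_factor(tbl)
  r1 <- rg$table[rg$table$parameter == "coating_thickness", ]
  r2 <- rg$table[rg$table$parameter == "probe_length", ]
  expect_true(r1$ci_lo < 2 && 2 < r1$ci_hi)
  expect_true(r2$ci_lo < -3 && -3 < r2$ci_hi)
  tbl$coating_thickness <- 5
  expect_error(regress_safety_factor(tbl), class = "pf_collinearity_error")
})
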