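test_that("safety factor is the buckling-to-insertion force ratio", {
  expect_equal(safety_factor(1, 1), 1)
  expect_equal(safety_factor(2e-3, 1e-3), 2)
  expect_error(safety_factor(0, 1), class = "pf_domain_error")
  expect_error(safety_factor(1, -2), class = "pf_domain_error")
})

test_that("bigger coatings on the same probe raise the safety factor", {
  rat <- load_cohort_fixtures("rat")
  sf <- function(co) {
    pr <- predict_insertion(co$assembly, tissue_preset("brain"))
    pr$safety_factor
  }
  expect_gt(sf(rat[[6]]), sf(rat[[4]]))   # 100x100 vs 50x100 coating
})

test_that("logistic fit recovers known parameters from synthetic cohorts", {
  set.seed(11)
  k_true <- 3; m_true <- 1.4
  est <- replicate(200, {
    f <- fit_logistic(synth_cohorts(k_true, m_true))
    c(f$midpoint, f$slope)
  })
  # unbiased within 2 standard errors of the replicate mean, and within 10%
  for (i in 1:2) {
    truth <- c(m_true, k_true)[i]
    se <- sd(est[i, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[i, ]) - truth), 2 * se + 0.02 * truth)
    expect_lt(abs(mean(est[i, ]) - truth) / truth, 0.1)
  }
})

test_that("complete separation errors without ridge and fits with it", {
  pts <- data.frame(safety_factor = c(0.5, 0.8, 2.5, 3),
                    n_pass = c(0, 0, 8, 8), n_total = 8)
  expect_error(fit_logistic(pts), class = "pf_separation_error")
  fit <- fit_logistic(pts, ridge = 1e-2)
  expect_gt(fit$slope, 0)
  expect_gt(fit$midpoint, 0.8)
  expect_lt(fit$midpoint, 2.5)
})

test_that("insufficient data is rejected", {
  expect_error(fit_logistic(data.frame(safety_factor = c(1, 1),
                                       n_pass = c(1, 5), n_total = 8)),
               class = "pf_insufficient_data")
})

test_that("logistic predictions behave as a proper sigmoid", {
  set.seed(3)
  fit <- fit_logistic(synth_cohorts(4, 1.2))
  expect_equal(predict_probability(fit, fit$midpoint), 0.5)
  expect_gt(predict_probability(fit, 50), 0.999)
  expect_equal(predict_probability(fit, sf_at_probability(fit, 0.99)), 0.99)
  sf <- seq(0, 5, by = 0.1)
  expect_true(all(diff(predict_probability(fit, sf)) > 0))
})

test_that("a new success at high safety factor never lowers upper-tail p", {
  set.seed(5)
  pts <- synth_cohorts(3, 1.4)
  f0 <- fit_logistic(pts)
  pts2 <- rbind(pts, data.frame(safety_factor = 4, n_pass = 50, n_total = 50))
  f1 <- fit_logistic(pts2)
  expect_gte(predict_probability(f1, 4.5), predict_probability(f0, 4.5) - 1e-6)
})

test_that("cohort pipeline yields a deterministic, classifying fit", {
  tbl <- cohort_safety_factors()
  expect_equal(nrow(tbl), 22)
  fit1 <- fit_logistic(tbl)
  fit2 <- fit_logistic(tbl)
  expect_identical(fit1$midpoint, fit2$midpoint)
  expect_gt(fit1$slope, 0)
})
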