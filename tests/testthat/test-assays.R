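test_that("calibration inversion reproduces hand arithmetic", {
  glc <- glucose_standard_curve()
  expect_equal(invert_calibration(0.0685, glc), 0)
  expect_equal(invert_calibration(42.5355, glc), 1.0)
  bsa <- bsa_standard_curve()
  expect_equal(invert_calibration(0.402, bsa), 10.0)
  # exact round trip for random concentrations
  set.seed(2)
  C <- runif(20, 0, 5)
  expect_equal(invert_calibration(glc$slope * C + glc$intercept, glc), C)
  expect_error(calibration_curve(0, 0.1), "non-zero")
})

test_that("extraction yield follows the mass-balance arithmetic", {
  expect_equal(extraction_yield(0, 400, 10, 20), 0)
  expect_equal(extraction_yield(0.5, 400, 10, 20), 10)  # 2 g from 20 g
  expect_equal(extraction_yield(0.5, 400, 20, 20),
               2 * extraction_yield(0.5, 400, 10, 20))
  expect_error(extraction_yield(0.5, 400, 10, 0), "positive")
})

test_that("scavenging rate matches its defining formula", {
  expect_equal(scavenging_rate(1.0, 0, 1.0), 0)
  expect_equal(scavenging_rate(0.3, 0.3, 0.8), 100)
  expect_equal(scavenging_rate(0.52, 0.02, 1.0), 50)
  # affine monotonicity: decreasing in the sample reading, increasing
  # in the blank
  expect_true(scavenging_rate(0.6, 0.02, 1) < scavenging_rate(0.5, 0.02, 1))
  expect_true(scavenging_rate(0.5, 0.05, 1) > scavenging_rate(0.5, 0.02, 1))
  expect_error(scavenging_rate(0.5, 0.02, 0), "positive")
})

test_that("an exact symmetric logistic is recovered to its midpoint", {
  x <- c(2, 4, 6, 8, 10, 14, 18, 25)
  y <- logistic4(x, 0, 100, 10, 2)
  fit <- estimate_ic50(x, y)
  expect_equal(fit$method, "4PL")
  expect_equal(fit$ic50, 10, tolerance = 1e-6)
})

test_that("ic50 is the 50 percent crossing, not the 4PL midpoint", {
  # asymmetric plateau: crossing at ec50 * ((top-bottom)/50 - 1)^(-1/hill)
  x <- c(2, 5, 8, 12, 16, 20, 30, 40)
  y <- logistic4(x, 0, 85, 13.2, 1.5)
  truth <- 13.2 * (85 / 50 - 1)^(-1 / 1.5)
  fit <- estimate_ic50(x, y)
  expect_equal(fit$ic50, truth, tolerance = 1e-4)
})

test_that("ic50 recovery tolerates measurement noise", {
  # noisy 4PL curves: recovered ic50 within 10 % of truth in >= 95 % of
  # simulations
  doses <- c(2, 4, 7, 10, 14, 18, 24, 30)
  truth <- 13.2 * (85 / 50 - 1)^(-1 / 1.5)
  ok <- vapply(1:100, function(s) {
    d <- generate_dose_response(0, 85, 13.2, 1.5, doses, noise_sd = 2,
                                seed = s)
    fit <- suppressWarnings(estimate_ic50(d$concentration, d$response))
    is.finite(fit$ic50) && abs(fit$ic50 - truth) / truth <= 0.10
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("ic50 estimation is scale equivariant", {
  x <- c(2, 5, 8, 12, 16, 20, 30, 40)
  y <- logistic4(x, 5, 92, 11, 1.8)
  base <- estimate_ic50(x, y)$ic50
  for (k in c(0.1, 3, 42)) {
    expect_equal(estimate_ic50(k * x, y)$ic50, k * base,
                 tolerance = 1e-6 * k * base)
  }
})

test_that("curves that never reach 50 percent are flagged undefined", {
  x <- c(1, 2, 4, 8, 16)
  y <- c(5, 12, 20, 28, 38)
  fit <- estimate_ic50(x, y)
  expect_false(fit$defined)
  expect_true(is.na(fit$ic50))
  expect_error(estimate_ic50(c(1, 2, 3), c(10, 50, 90)), "at least 4")
  expect_error(estimate_ic50(c(-1, 2, 3, 4), c(10, 40, 60, 90)),
               "positive")
})

test_that("out-of-range responses are clipped with a warning", {
  x <- c(1, 3, 6, 12, 24, 48)
  y <- c(-8, 10, 35, 60, 90, 108)
  expect_warning(fit <- estimate_ic50(x, y), "clipped")
  expect_true(is.finite(fit$ic50))
})

test_that("a near-step curve still brackets its midpoint", {
  x <- c(2, 4, 6, 8, 10, 12, 16, 20)
  y <- generate_dose_response(0, 100, 9, 50, x, seed = 1)$response
  fit <- suppressWarnings(estimate_ic50(x, y))
  expect_true(fit$ic50 > 8 && fit$ic50 < 10)
})
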