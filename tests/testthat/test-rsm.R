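test_that("quadratic expansion has the fixed term structure", {
  M <- expand_quadratic(matrix(0, 1, 5))
  expect_equal(unname(M[1, ]), c(1, rep(0, 20)))
  expect_equal(ncol(M), 21)

  M <- expand_quadratic(matrix(c(1, 1, 0, 0, 0), 1, 5))
  expect_equal(unname(M[1, "X1:X2"]), 1)
  expect_equal(unname(M[1, "X3:X4"]), 0)

  # the bundled design supports all 21 terms
  expect_equal(qr(expand_quadratic(code_design(rlmp_design())))$rank, 21)

  expect_error(expand_quadratic(matrix(NA_real_, 2, 5)), "finite")
})

test_that("noise-free quadratic data are recovered exactly", {
  spec <- surface_spec(noise_sd = 0, seed = 7)
  tab <- generate_design_response(spec)
  fit <- fit_quadratic(tab)
  expect_equal(unname(fit$coef_coded), unname(spec$true_coefficients),
               tolerance = 1e-8)
  a <- rsm_anova(fit, tab)
  expect_equal(a$summary$r2, 1, tolerance = 1e-12)
})

test_that("fit diagnostics satisfy the OLS identities", {
  fit <- fit_quadratic(rlmp_design())
  expect_lt(abs(sum(fit$residuals)), 1e-8)
  expect_equal(sum(fit$leverage), 21, tolerance = 1e-6)
  expect_true(all(fit$leverage > 0 & fit$leverage < 1))
  # coded and actual coefficient sets describe the same surface
  X <- design_actual(rlmp_design())
  pred_coded <- predict(fit, code_design(rlmp_design()), scale = "coded")
  pred_actual <- predict(fit, X)
  expect_equal(pred_coded, pred_actual, tolerance = 1e-6)
})

test_that("under-determined and rank-deficient fits are rejected", {
  tab <- rlmp_design()
  small <- design_table(tab$factors, design_actual(tab)[1:10, ],
                        design_response(tab)[1:10])
  expect_error(fit_quadratic(small), "nder-determined")
  noresp <- build_bbd(rlmp_factors(), 6)
  expect_error(fit_quadratic(noresp), "responses")
})

test_that("actual-unit conversion leaves predictions invariant", {
  fit <- fit_quadratic(rlmp_design())
  # direct evaluation of the actual-unit polynomial
  X <- design_actual(rlmp_design())
  Ma <- expand_quadratic(X)
  pred_a <- drop(Ma %*% fit$coef_actual)
  expect_equal(pred_a, fit$fitted, tolerance = 1e-6)

  # identity coding: actual equals coded
  f_id <- setNames(lapply(paste0("X", 1:5), function(s)
    factor_spec(s, s, "", -1, 0, 1)), paste0("X", 1:5))
  set.seed(1)
  tab_id <- generate_design_response(
    surface_spec(rnorm(21), noise_sd = 0.1, factors = f_id, seed = 2))
  fit_id <- fit_quadratic(tab_id)
  expect_equal(fit_id$coef_actual, fit_id$coef_coded, tolerance = 1e-10)
})

test_that("center prediction tracks the replicate mean", {
  fit <- fit_quadratic(rlmp_design())
  center <- c(30, 20, 180, 40, 0.55)
  # OLS at an exactly replicated point tracks the replicate mean (10.717)
  expect_lt(abs(predict(fit, center) - 10.72), 0.1)
  # the published rounded actual-unit equation evaluates to 10.763 at the
  # center; its rounding error against the full-precision refit stays
  # below 0.05 % yield there
  printed <- c(-167.345, 1.657, 2.076, 1.044, 1.399, 35.173,
               -0.0153, -0.00161, 0.000325, 0.244, 0.0018, 0.00535,
               -0.295, -0.000725, -0.0904, 0.0433,
               -0.0190, -0.0492, -0.00268, -0.0173, -19.488)
  eq_val <- drop(expand_quadratic(matrix(center, 1, 5)) %*% printed)
  expect_equal(eq_val, 10.763, tolerance = 1e-3)
  expect_lt(abs(eq_val - predict(fit, center)), 0.05)
})

test_that("prediction guards inputs and warns on extrapolation", {
  fit <- fit_quadratic(rlmp_design())
  expect_error(predict(fit, c(30, 20, 180, 40, NA)), "finite")
  expect_warning(predict(fit, c(50, 20, 180, 40, 0.55)), "cube")
  const <- fit
  const$coef_coded[] <- 0
  const$coef_coded["(Intercept)"] <- 3.5
  expect_equal(predict(const, c(25, 18, 170, 35, 0.3)), 3.5)
})

test_that("ANOVA additivity identities hold on every fit", {
  for (seed in 1:3) {
    tab <- generate_design_response(surface_spec(seed = seed))
    fit <- fit_quadratic(tab)
    a <- rsm_anova(fit, tab)
    r <- a$rows
    ss <- function(src) r$ss[r$source == src]
    expect_equal(ss("Model") + ss("Residual"), ss("Cor Total"),
                 tolerance = 1e-6 * ss("Cor Total"))
    expect_equal(ss("Lack of Fit") + ss("Pure Error"), ss("Residual"),
                 tolerance = 1e-6 * max(ss("Residual"), 1e-12))
    expect_equal(r$df[r$source == "Model"], 20)
    expect_equal(r$df[r$source == "Residual"], 46 - 21)
    expect_equal(r$df[r$source == "Pure Error"], 5)
    expect_equal(a$summary$r2, 1 - ss("Residual") / ss("Cor Total"))
  }
})

test_that("partial SS equals the SS drop from deleting the term (oracle)", {
  # brute-force oracle on a 3-factor, 15-run BBD
  f3 <- rlmp_factors()[1:3]
  set.seed(11)
  truth <- rnorm(10)
  tab <- generate_design_response(
    surface_spec(truth, noise_sd = 0.1, n_center = 3, factors = f3,
                 seed = 3))
  fit <- fit_quadratic(tab)
  y <- design_response(tab)
  M <- expand_quadratic(code_design(tab))
  XtX_inv <- chol2inv(chol(crossprod(M)))
  ss_full <- sum(lm.fit(M, y)$residuals^2)
  for (j in 2:ncol(M)) {
    ss_drop <- sum(lm.fit(M[, -j, drop = FALSE], y)$residuals^2) - ss_full
    ss_partial <- fit$coef_coded[j]^2 / XtX_inv[j, j]
    expect_equal(unname(ss_partial), ss_drop,
                 tolerance = 1e-8 * max(ss_drop, 1e-8))
  }
})

test_that("BBD orthogonality makes partial and sequential SS agree", {
  # linear and interaction columns of the BBD are mutually orthogonal,
  # so each term's partial SS equals its sequential SS
  tab <- rlmp_design()
  fit <- fit_quadratic(tab)
  a <- rsm_anova(fit, tab)
  y <- design_response(tab)
  M <- expand_quadratic(code_design(tab))
  seq_terms <- fit$term_order[2:16]  # linear + interactions
  for (j in seq_along(seq_terms)) {
    cols <- 1:(1 + j)
    ss_seq <- sum(lm.fit(M[, 1:(cols[length(cols)] - 1), drop = FALSE],
                         y)$residuals^2) -
      sum(lm.fit(M[, cols, drop = FALSE], y)$residuals^2)
    ss_part <- a$rows$ss[a$rows$source == seq_terms[j]]
    expect_equal(ss_part, ss_seq, tolerance = 1e-6 * max(ss_seq, 1e-6))
  }
})

test_that("lack-of-fit requires replicates and flags their absence", {
  f3 <- rlmp_factors()[1:3]
  tab <- generate_design_response(
    surface_spec(rnorm(10), noise_sd = 0.1, n_center = 1, factors = f3,
                 seed = 5))
  fit <- fit_quadratic(tab)
  a <- rsm_anova(fit, tab)
  expect_false("Lack of Fit" %in% a$rows$source)
  expect_match(a$flags, "replicate", all = FALSE)
})

test_that("maximize_quadratic recovers analytic optima", {
  fit <- fit_quadratic(rlmp_design())
  # concave paraboloid with known interior vertex
  syms <- paste0("X", 1:5)
  vertex <- c(0.3, -0.2, 0.5, -0.4, 0.1)
  beta <- setNames(numeric(21), fit$term_order)
  beta["(Intercept)"] <- 5
  beta[paste0(syms, "^2")] <- -1
  beta[syms] <- 2 * vertex
  toy <- fit
  toy$coef_coded <- beta
  opt <- maximize_quadratic(toy)
  expect_equal(unname(opt$conditions_coded), vertex, tolerance = 1e-6)
  expect_equal(opt$predicted_yield, 5 + sum(vertex^2), tolerance = 1e-9)

  # vertex outside the box lands on the boundary
  beta[syms] <- c(4, 0, 0, 0, 0)  # vertex at X1 = 2
  toy$coef_coded <- beta
  opt2 <- maximize_quadratic(toy)
  expect_equal(unname(opt2$conditions_coded[1]), 1, tolerance = 1e-8)

  expect_error(maximize_quadratic(fit, lower = c(0, 0, 0, 0, 0),
                                  upper = c(1, 1, 1, -1, 1)), "box")
})

test_that("ANOVA serializes to JSON and aligned text", {
  fit <- fit_quadratic(rlmp_design())
  a <- rsm_anova(fit, rlmp_design())
  js <- jsonlite::fromJSON(anova_json(a))
  expect_equal(nrow(js$rows), 25)  # model + 20 terms + res + lof + pe + total
  expect_equal(js$summary$r2, a$summary$r2, tolerance = 1e-12)
  txt <- anova_text(a)
  expect_match(txt, "Lack of Fit", all = FALSE)
  expect_match(txt, "< 0.0001", all = FALSE)
})
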