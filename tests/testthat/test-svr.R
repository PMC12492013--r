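make_norm_data <- function() {
  tab <- rlmp_design()
  b <- fit_bounds(tab)
  list(tab = tab, b = b,
       X = normalize_x(design_actual(tab), b),
       y = normalize_y(design_response(tab), b))
}

# dual objective of the epsilon-SVR, for oracle comparisons
dual_objective <- function(K, y, beta, epsilon) {
  0.5 * drop(t(beta) %*% K %*% beta) + epsilon * sum(abs(beta)) -
    sum(y * beta)
}

test_that("min-max normalization maps bounds to 0/1 and inverts exactly", {
  d <- make_norm_data()
  expect_equal(unname(normalize_x(d$b$x_min, d$b)[1, ]), rep(0, 5))
  expect_equal(unname(normalize_x(d$b$x_max, d$b)[1, ]), rep(1, 5))
  expect_equal(normalize_y(10.88, d$b), 1)  # the maximum observed yield
  set.seed(3)
  V <- matrix(runif(50, -2, 3), 10, 5)
  expect_equal(denormalize_x(normalize_x(V, d$b), d$b), V,
               tolerance = 1e-12)
  yy <- runif(10, 0, 20)
  expect_equal(denormalize_y(normalize_y(yy, d$b), d$b), yy,
               tolerance = 1e-12)
})

test_that("constant columns are rejected with the offending name", {
  tab <- rlmp_design()
  tab$runs$X2 <- 20
  expect_error(fit_bounds(tab), "X2")
})

test_that("the RBF kernel is a proper similarity", {
  expect_equal(rbf_kernel(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0), 1),
               exp(-1))
  set.seed(4)
  for (i in 1:10) {
    a <- runif(5); b <- runif(5)
    expect_equal(rbf_kernel(a, a, 2), 1)
    expect_equal(rbf_kernel(a, b, 2), rbf_kernel(b, a, 2))
    expect_true(rbf_kernel(a, b, 2) > 0 && rbf_kernel(a, b, 2) <= 1)
  }
  expect_error(rbf_kernel(c(NA, 1), c(0, 1), 1), "finite")
})

test_that("a realizable relation is fitted within the tube", {
  X <- cbind(seq(0, 1, length.out = 5), 0.5, 0.5, 0.5, 0.5)
  y <- X[, 1]
  m <- train_svr(X, y, C = 1000, gamma = 2, epsilon = 0.01)
  expect_true(all(abs(predict_svr(m, X) - y) <= 0.011))
})

test_that("KKT conditions hold on trained models", {
  d <- make_norm_data()
  for (prm in list(c(1, 1), c(10, 5), c(100, 10))) {
    m <- train_svr(d$X, d$y, C = prm[1], gamma = prm[2], epsilon = 0.01)
    # box feasibility and the equality constraint
    expect_true(all(abs(m$dual_coefficients) <= prm[1] + 1e-8))
    expect_lt(abs(sum(m$dual_coefficients)), 1e-6)
    # complementary slackness: strictly-inside-tube points have zero dual
    pred <- predict_svr(m, d$X)
    inside <- abs(d$y - pred) < m$epsilon - 1e-6
    dual_full <- numeric(nrow(d$X))
    dual_full[m$support_index] <- m$dual_coefficients
    expect_true(all(abs(dual_full[inside]) <= 1e-6))
    # bound-support points sit on or beyond their tube edge
    atC <- which(dual_full >= m$C - 1e-6 * m$C)
    expect_true(all(pred[atC] <= d$y[atC] - m$epsilon + 1e-5))
  }
})

test_that("the trained dual matches an independent solver's objective", {
  skip_if_not_installed("e1071")
  d <- make_norm_data()
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    idx <- sample(nrow(d$X), n)
    X <- d$X[idx, ]; y <- d$y[idx]
    C <- 10^runif(1, -1, 2); gamma <- 10^runif(1, -1, 1.5)
    m <- train_svr(X, y, C = C, gamma = gamma, epsilon = 0.01)
    K <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], gamma)))
    beta <- numeric(n)
    beta[m$support_index] <- m$dual_coefficients
    sv <- e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", cost = C, gamma = gamma,
                     epsilon = 0.01, scale = FALSE, tolerance = 1e-8)
    beta_ref <- numeric(n); beta_ref[sv$index] <- sv$coefs
    o_mine <- dual_objective(K, y, beta, 0.01)
    o_ref <- dual_objective(K, y, beta_ref, 0.01)
    expect_equal(o_mine, o_ref, tolerance = 1e-6 * max(abs(o_ref), 1e-6))
  }
})

test_that("training error is non-increasing in C", {
  d <- make_norm_data()
  rmse <- vapply(c(0.1, 1, 10, 100), function(C) {
    m <- train_svr(d$X, d$y, C = C, gamma = 5, epsilon = 0.01)
    sqrt(mean((d$y - predict_svr(m, d$X))^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-8))
})

test_that("gamma -> 0 collapses predictions to a constant", {
  d <- make_norm_data()
  m <- train_svr(d$X, d$y, C = 10, gamma = 1e-8, epsilon = 0.01)
  pred <- predict_svr(m, d$X)
  expect_lt(diff(range(pred)), 1e-3)
  # that constant is the epsilon-insensitive location of the targets
  expect_lt(abs(mean(pred) - mean(range(d$y))), 0.5)
})

test_that("degenerate constant targets yield a constant model", {
  X <- matrix(runif(25), 5, 5)
  m <- train_svr(X, rep(0.4, 5), C = 10, gamma = 1, epsilon = 0.01)
  expect_equal(nrow(m$support_points), 0)
  expect_equal(predict_svr(m, X), rep(0.4, 5))
})

test_that("raw-scale prediction denormalizes through the stored bounds", {
  d <- make_norm_data()
  m <- train_svr(d$X, d$y, C = 100, gamma = 10, epsilon = 0.01,
                 bounds = d$b)
  raw <- predict_svr(m, design_actual(d$tab), scale = "raw")
  norm <- predict_svr(m, d$X)
  expect_equal(raw, denormalize_y(norm, d$b), tolerance = 1e-12)
  expect_gt(regression_metrics(design_response(d$tab), raw)$r2, 0.99)
  m_nb <- train_svr(d$X, d$y, C = 1, gamma = 1)
  expect_error(predict_svr(m_nb, d$X, scale = "raw"), "bounds")
})

test_that("metric definitions match hand arithmetic", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$mae, 1 / 3)
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(perfect$r2, perfect$rmse, perfect$mae), c(1, 0, 0))
  at_mean <- regression_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(at_mean$r2, 0)
  expect_warning(m0 <- regression_metrics(c(2, 2), c(1, 3)), "constant")
  expect_true(is.na(m0$r2))
  expect_true(m0$rmse >= m0$mae)
})

test_that("SVR models serialize to JSON and back-predict", {
  d <- make_norm_data()
  m <- train_svr(d$X, d$y, C = 10, gamma = 5, epsilon = 0.01, bounds = d$b)
  js <- jsonlite::fromJSON(svr_model_json(m))
  expect_equal(js$bias, m$bias, tolerance = 1e-12)
  expect_equal(length(js$dual_coefficients), nrow(m$support_points))
})
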