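# Epsilon-insensitive support vector regression with an RBF kernel.
#
# Training solves the standard dual (box constraints [0, C] on alpha and
# alpha*, one equality constraint) by sequential minimal optimization in
# compiled code; see src/smo.cpp. Inputs and response are min-max
# normalized to [0, 1] before training.

#' Min-max normalization bounds for a design table
#'
#' @param table A [design_table()] with responses.
#' @return An object of class `norm_bounds` with `x_min`, `x_max`
#'   (per-factor, actual units) and `y_min`, `y_max` (response scale).
#' @export
fit_bounds <- function(table) {
  stopifnot(inherits(table, "design_table"))
  X <- design_actual(table)
  y <- design_response(table)
  y <- y[!is.na(y)]
  if (!length(y)) stop("no responses to derive y bounds from", call. = FALSE)
  b <- structure(list(x_min = apply(X, 2, min), x_max = apply(X, 2, max),
                      y_min = min(y), y_max = max(y)),
                 class = "norm_bounds")
  const <- which(b$x_max - b$x_min <= 0)
  if (length(const))
    stop("constant input columns cannot be normalized: ",
         paste(names(b$x_min)[const], collapse = ", "), call. = FALSE)
  if (b$y_max <= b$y_min)
    stop("constant response cannot be normalized", call. = FALSE)
  b
}

#' Min-max normalize or restore inputs and responses
#'
#' Componentwise `(v - min) / (max - min)`; values at the minimum map to 0
#' and at the maximum to 1. The denormalizers are exact inverses.
#'
#' @param X Matrix (or single row vector) of actual-unit inputs.
#' @param y Numeric response vector.
#' @param bounds A `norm_bounds` object from [fit_bounds()].
#' @return Transformed matrix or vector.
#' @export
normalize_x <- function(X, bounds) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(sweep(X, 2, bounds$x_min), 2, bounds$x_max - bounds$x_min, "/")
}

#' @rdname normalize_x
#' @export
denormalize_x <- function(X, bounds) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(sweep(X, 2, bounds$x_max - bounds$x_min, "*"), 2, bounds$x_min, "+")
}

#' @rdname normalize_x
#' @export
normalize_y <- function(y, bounds) {
  (y - bounds$y_min) / (bounds$y_max - bounds$y_min)
}

#' @rdname normalize_x
#' @export
denormalize_y <- function(y, bounds) {
  y * (bounds$y_max - bounds$y_min) + bounds$y_min
}

#' Gaussian radial basis kernel
#'
#' `K(a, b) = exp(-gamma * ||a - b||^2)`, in (0, 1] and symmetric.
#'
#' @param a,b Numeric vectors of equal length.
#' @param gamma Kernel width parameter, > 0.
#' @return Kernel value.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), 1)  # exp(-1)
#' @export
rbf_kernel <- function(a, b, gamma) {
  stopifnot(gamma > 0)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite kernel inputs", call. = FALSE)
  exp(-gamma * sum((a - b)^2))
}

# Cross-kernel matrix between row sets A (n x d) and B (m x d).
rbf_kernel_matrix <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Train an epsilon-SVR with RBF kernel
#'
#' Solves the epsilon-insensitive dual by sequential minimal optimization
#' (maximal-violating-pair working-set selection, compiled inner loop).
#' The bias is recovered from the Karush-Kuhn-Tucker interval implied by
#' the trained dual coefficients; with free support vectors this interval
#' collapses to the usual free-vector average. Only points with
#' non-negligible dual coefficient are stored as support points.
#'
#' @param X n-by-d matrix of (normalized) inputs.
#' @param y Length-n (normalized) response.
#' @param C Regularization parameter, > 0.
#' @param gamma RBF kernel width, > 0.
#' @param epsilon Insensitive-tube half width on the training scale
#'   (default 0.01, intended for min-max normalized responses).
#' @param tol KKT tolerance for the solver.
#' @param max_iter Iteration cap; non-convergence is reported with the
#'   residual KKT gap.
#' @param bounds Optional `norm_bounds` carried along so the model can
#'   predict from, and report on, the raw scale.
#' @return An object of class `svr_model`.
#' @export
train_svr <- function(X, y, C, gamma, epsilon = 0.01, tol = 1e-6,
                      max_iter = 1e5, bounds = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), C > 0, gamma > 0, epsilon >= 0)
  if (nrow(X) < 2) stop("need at least 2 training points", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite training data", call. = FALSE)
  if (diff(range(y)) == 0) {
    # degenerate: all targets identical; the constant y is optimal
    return(structure(list(support_points = X[0, , drop = FALSE],
                          dual_coefficients = numeric(0),
                          support_index = integer(0),
                          bias = y[1], C = C, gamma = gamma,
                          epsilon = epsilon, bounds = bounds,
                          iterations = 0L, kkt_gap = 0, converged = TRUE),
                     class = "svr_model"))
  }
  K <- rbf_kernel_matrix(X, X, gamma)
  sol <- smo_solve(K, y, C, epsilon, tol, as.integer(max_iter))
  if (!sol$converged)
    warning(sprintf("SMO hit the iteration cap (%d); residual KKT gap %.2e",
                    sol$iterations, sol$kkt_gap))
  beta <- sol$beta
  fx <- drop(K %*% beta)
  bias <- svr_bias(beta, y - fx, C, epsilon)
  keep <- abs(beta) > 1e-10
  structure(list(support_points = X[keep, , drop = FALSE],
                 dual_coefficients = beta[keep],
                 support_index = which(keep),
                 bias = bias, C = C, gamma = gamma, epsilon = epsilon,
                 bounds = bounds,
                 iterations = sol$iterations, kkt_gap = sol$kkt_gap,
                 converged = sol$converged),
            class = "svr_model")
}

# KKT interval for the bias: each training point constrains
# e_i = y_i - (K beta)_i - b according to its dual coefficient; the
# returned bias is the midpoint of the feasible interval.
svr_bias <- function(beta, e_minus_b, C, epsilon) {
  lb <- rep(-epsilon, length(beta))  # e_i lower bound
  ub <- rep(epsilon, length(beta))
  tolC <- 1e-8 * max(C, 1)
  atC <- beta >= C - tolC
  atmC <- beta <= -C + tolC
  posf <- beta > 1e-10 & !atC
  negf <- beta < -1e-10 & !atmC
  lb[posf] <- epsilon; ub[posf] <- epsilon
  lb[negf] <- -epsilon; ub[negf] <- -epsilon
  lb[atC] <- epsilon; ub[atC] <- Inf
  lb[atmC] <- -Inf; ub[atmC] <- -epsilon
  lo <- max(e_minus_b - ub)   # b >= e - ub
  hi <- min(e_minus_b - lb)   # b <= e - lb
  (lo + hi) / 2
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("epsilon-SVR (RBF): C = %g, gamma = %g, epsilon = %g\n",
              x$C, x$gamma, x$epsilon))
  cat(sprintf("%d support points, bias %.5f, KKT gap %.2e\n",
              nrow(x$support_points), x$bias, x$kkt_gap))
  invisible(x)
}

#' Predict from a trained epsilon-SVR
#'
#' @param model An `svr_model`.
#' @param X Points to predict at, one row each. On scale `"normalized"`
#'   these are in the model's training (normalized) units; on `"raw"` they
#'   are actual-unit points, normalized through the model's stored bounds,
#'   and predictions are returned denormalized to the response scale.
#' @param scale `"normalized"` or `"raw"`.
#' @return Numeric vector of predictions.
#' @export
predict_svr <- function(model, X, scale = c("normalized", "raw")) {
  stopifnot(inherits(model, "svr_model"))
  scale <- match.arg(scale)
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (scale == "raw") {
    if (is.null(model$bounds))
      stop("model carries no normalization bounds; cannot predict on raw scale",
           call. = FALSE)
    X <- normalize_x(X, model$bounds)
  }
  pred <- if (nrow(model$support_points) == 0) {
    rep(model$bias, nrow(X))
  } else {
    drop(rbf_kernel_matrix(X, model$support_points, model$gamma) %*%
           model$dual_coefficients) + model$bias
  }
  if (scale == "raw") denormalize_y(pred, model$bounds) else pred
}

#' @export
predict.svr_model <- function(object, newdata,
                              scale = c("normalized", "raw"), ...) {
  predict_svr(object, newdata, scale)
}

#' Goodness-of-fit metrics for predictions
#'
#' The coefficient of determination `R2 = 1 - SS_err / SS_tot`, the root
#' mean square error, and the mean absolute error, with no
#' degrees-of-freedom adjustment.
#'
#' @param y_true,y_pred Equal-length numeric vectors; R-squared needs at
#'   least two distinct `y_true` values and is flagged undefined otherwise.
#' @param scale_note Label recording the scale the metrics are computed
#'   on, e.g. `"raw (%)"` or `"normalized"`.
#' @return A list of class `metric_set`: `r2`, `rmse`, `mae`, `n`,
#'   `scale_note`, and `r2_defined`.
#' @export
regression_metrics <- function(y_true, y_pred, scale_note = "raw (%)") {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  err <- y_true - y_pred
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  sst <- sum((y_true - mean(y_true))^2)
  r2_defined <- length(y_true) >= 2 && sst > 0
  r2 <- if (r2_defined) 1 - sum(err^2) / sst else NA_real_
  if (!r2_defined)
    warning("constant y_true: R2 is undefined")
  structure(list(r2 = r2, rmse = rmse, mae = mae, n = length(y_true),
                 scale_note = scale_note, r2_defined = r2_defined),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 %.4f  RMSE %.4f  MAE %.4f  (n = %d, %s)\n",
              x$r2, x$rmse, x$mae, x$n, x$scale_note))
  invisible(x)
}

#' Serialize a trained SVR model to JSON
#'
#' @param model An `svr_model`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
svr_model_json <- function(model, path = NULL) {
  x <- list(support_points = unname(as.matrix(model$support_points)),
            dual_coefficients = model$dual_coefficients,
            bias = model$bias, C = model$C, gamma = model$gamma,
            epsilon = model$epsilon,
            bounds = if (!is.null(model$bounds))
              lapply(unclass(model$bounds), unname))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
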