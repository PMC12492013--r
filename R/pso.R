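# Particle swarm optimization with the classic inertia-weight velocity
# update
#
#   v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)
#   x <- x + v
#
# where r1, r2 are fresh uniforms per particle per iteration (scalar by
# default, switchable to per-dimension). Positions are clipped to the box
# after each move with the clipped velocity component zeroed, and
# velocities are clamped at half the box width per dimension -- at
# w = 0.8, c1 = c2 = 2 the swarm diverges without a clamp.

#' Particle swarm configuration
#'
#' Defaults follow the common process-optimization setup: inertia weight
#' 0.8, cognitive and social learning factors 2, 50 particles, 50
#' iterations, and convergence declared when the global best improves by
#' less than `tol` over `patience` consecutive generations.
#'
#' @param inertia Inertia weight w.
#' @param cognitive,social Learning factors c1, c2.
#' @param swarm_size Number of particles (>= 2).
#' @param max_iterations Iteration cap.
#' @param tol Convergence tolerance on the global best value.
#' @param patience Generations over which the improvement is measured.
#' @param r_mode `"scalar"` draws one r1 and one r2 per particle per
#'   iteration; `"per_dimension"` draws one pair per coordinate.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(inertia = 0.8, cognitive = 2, social = 2,
                       swarm_size = 50, max_iterations = 50,
                       tol = 1e-4, patience = 10,
                       r_mode = c("scalar", "per_dimension")) {
  stopifnot(swarm_size >= 2, max_iterations >= 1, tol > 0, patience >= 1)
  structure(list(inertia = inertia, cognitive = cognitive, social = social,
                 swarm_size = as.integer(swarm_size),
                 max_iterations = as.integer(max_iterations),
                 tol = tol, patience = as.integer(patience),
                 r_mode = match.arg(r_mode)),
            class = "pso_config")
}

#' Has a global-best history converged?
#'
#' `TRUE` iff the history has at least `patience + 1` entries and the drop
#' over the last `patience` generations is smaller than `tol`.
#'
#' @param history Numeric vector of per-iteration global best values.
#' @param tol Tolerance.
#' @param patience Number of generations.
#' @return Logical flag.
#' @export
pso_converged <- function(history, tol = 1e-4, patience = 10) {
  stopifnot(length(history) >= 1)
  m <- length(history)
  if (m < patience + 1) return(FALSE)
  (history[m - patience] - history[m]) < tol
}

#' Minimize an objective over a box by particle swarm
#'
#' Positions are initialized uniformly in the box and velocities at zero;
#' the run is deterministic for a fixed `seed`. Terminates at
#' `max_iterations` or when the global best value stalls (see
#' [pso_converged()]).
#'
#' @param objective Function mapping a d-vector to a finite scalar.
#' @param lower,upper Numeric bounds per dimension (`lower < upper`).
#' @param config A [pso_config()].
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A list of class `pso_result`: `best_position`, `best_value`,
#'   `history` (per-iteration global best), `iterations_run`,
#'   `converged`, `seed`.
#' @examples
#' r <- pso_minimize(function(x) sum(x^2), rep(-5, 3), rep(5, 3),
#'                   seed = 1)
#' r$best_value < 1e-3
#' @export
pso_minimize <- function(objective, lower, upper, config = pso_config(),
                         seed = NULL) {
  stopifnot(inherits(config, "pso_config"), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  d <- length(lower)
  S <- config$swarm_size
  vmax <- 0.5 * (upper - lower)
  eval_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v))
      stop("objective returned a non-finite value at (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    v
  }
  local_seed(seed, {
    X <- matrix(runif(S * d, rep(lower, each = S), rep(upper, each = S)),
                S, d)
    V <- matrix(0, S, d)
    pbest <- X
    pval <- apply(X, 1, eval_obj)
    g <- which.min(pval)
    gbest <- X[g, ]; gval <- pval[g]
    history <- numeric(0)
    iter <- 0L
    converged <- FALSE
    while (iter < config$max_iterations) {
      iter <- iter + 1L
      for (i in seq_len(S)) {
        if (config$r_mode == "scalar") {
          r1 <- runif(1); r2 <- runif(1)
        } else {
          r1 <- runif(d); r2 <- runif(d)
        }
        V[i, ] <- config$inertia * V[i, ] +
          config$cognitive * r1 * (pbest[i, ] - X[i, ]) +
          config$social * r2 * (gbest - X[i, ])
        V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
        xnew <- X[i, ] + V[i, ]
        clipped <- xnew < lower | xnew > upper
        xnew <- pmin(pmax(xnew, lower), upper)
        V[i, clipped] <- 0
        X[i, ] <- xnew
        f <- eval_obj(xnew)
        if (f < pval[i]) { pval[i] <- f; pbest[i, ] <- xnew }
        if (f < gval) { gval <- f; gbest <- xnew }
      }
      history <- c(history, gval)
      if (pso_converged(history, config$tol, config$patience)) {
        converged <- TRUE
        break
      }
    }
    structure(list(best_position = gbest, best_value = gval,
                   history = history, iterations_run = iter,
                   converged = converged, seed = seed),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("PSO: best value %.6g after %d iterations%s\n",
              x$best_value, x$iterations_run,
              if (x$converged) " (converged)" else ""))
  cat("position:", signif(x$best_position, 6), "\n")
  invisible(x)
}

#' Serialize a PSO result (including convergence history) to JSON
#'
#' @param result A `pso_result`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
pso_result_json <- function(result, path = NULL) {
  x <- unclass(result)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
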