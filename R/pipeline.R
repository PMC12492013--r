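# Orchestration of the surrogate-modeling workflow: normalize, split,
# PSO-tune (C, gamma), refit, search the surrogate for optimal process
# settings, and compare against the response-surface model.

#' Randomly split a design table into training and test runs
#'
#' Uniform shuffle under the seed; the first `round(ratio * n)` shuffled
#' runs form the training set (round-half-up, so 46 runs at ratio 0.8
#' give a 37/9 split).
#'
#' @param table A [design_table()] with at least 5 runs.
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return A list of class `split_indices`: `train_ids`, `test_ids`
#'   (run ids), `seed`, `ratio`.
#' @export
split_dataset <- function(table, ratio = 0.8, seed = NULL) {
  stopifnot(inherits(table, "design_table"))
  n <- nrow(table$runs)
  if (n < 5) stop("need at least 5 runs to split", call. = FALSE)
  if (!(ratio > 0 && ratio < 1))
    stop("ratio must be in (0, 1)", call. = FALSE)
  ids <- table$runs$run
  perm <- local_seed(seed, sample(ids))
  n_train <- floor(ratio * n + 0.5)  # round half up
  structure(list(train_ids = sort(perm[seq_len(n_train)]),
                 test_ids = sort(perm[-seq_len(n_train)]),
                 seed = seed, ratio = ratio),
            class = "split_indices")
}

# rows of `table` matching a set of run ids
rows_for_ids <- function(table, ids) {
  match(ids, table$runs$run)
}

#' Tune SVR hyperparameters by particle swarm optimization
#'
#' The objective is the held-out root mean square error on the normalized
#' scale: for a candidate (C, gamma), an epsilon-SVR is trained on the
#' training runs and evaluated on the test runs, and PSO minimizes that
#' error over the (C, gamma) box. The final model is refitted at the best
#' candidate, and metrics are reported on the raw (percent) scale for the
#' training, test, and full run sets.
#'
#' @param table A [design_table()] with responses.
#' @param split A [split_dataset()] result.
#' @param C_bounds,gamma_bounds Length-2 search intervals (default
#'   `[0.1, 100]` each).
#' @param config A [pso_config()] for the hyperparameter search.
#' @param epsilon Insensitive-tube half width on the normalized scale.
#' @param seed Seed for the PSO run.
#' @return A list of class `svr_tuning`: `best_C`, `best_gamma`,
#'   `objective_value` (test RMSE, normalized scale), `model` (the
#'   refitted `svr_model` carrying normalization bounds), `pso_result`,
#'   and `train_metrics` / `test_metrics` / `all_metrics` plus their
#'   normalized-scale counterparts in `metrics_normalized`.
#' @export
tune_svr <- function(table, split, C_bounds = c(0.1, 100),
                     gamma_bounds = c(0.1, 100), config = pso_config(),
                     epsilon = 0.01, seed = NULL) {
  stopifnot(inherits(table, "design_table"),
            inherits(split, "split_indices"),
            all(C_bounds > 0), all(gamma_bounds > 0))
  bounds <- fit_bounds(table)
  Xn <- normalize_x(design_actual(table), bounds)
  yn <- normalize_y(design_response(table), bounds)
  tr <- rows_for_ids(table, split$train_ids)
  te <- rows_for_ids(table, split$test_ids)
  objective <- function(p) {
    m <- tryCatch(
      train_svr(Xn[tr, , drop = FALSE], yn[tr], C = p[1], gamma = p[2],
                epsilon = epsilon),
      error = function(e)
        stop("SVR training failed at (C, gamma) = (",
             signif(p[1], 6), ", ", signif(p[2], 6), "): ",
             conditionMessage(e), call. = FALSE))
    sqrt(mean((yn[te] - predict_svr(m, Xn[te, , drop = FALSE]))^2))
  }
  pso <- pso_minimize(objective, c(C_bounds[1], gamma_bounds[1]),
                      c(C_bounds[2], gamma_bounds[2]), config, seed)
  best_C <- pso$best_position[1]
  best_gamma <- pso$best_position[2]
  model <- train_svr(Xn[tr, , drop = FALSE], yn[tr], C = best_C,
                     gamma = best_gamma, epsilon = epsilon, bounds = bounds)
  y_raw <- design_response(table)
  X_raw <- design_actual(table)
  pred_raw <- predict_svr(model, X_raw, scale = "raw")
  pred_n <- predict_svr(model, Xn)
  mk <- function(rows, scale_note, truth, pred)
    regression_metrics(truth[rows], pred[rows], scale_note)
  structure(list(
    best_C = best_C, best_gamma = best_gamma,
    objective_value = pso$best_value,
    model = model, pso_result = pso, split = split, epsilon = epsilon,
    train_metrics = mk(tr, "raw (%)", y_raw, pred_raw),
    test_metrics = mk(te, "raw (%)", y_raw, pred_raw),
    all_metrics = mk(seq_along(y_raw), "raw (%)", y_raw, pred_raw),
    metrics_normalized = list(
      train = mk(tr, "normalized", yn, pred_n),
      test = mk(te, "normalized", yn, pred_n),
      all = mk(seq_along(yn), "normalized", yn, pred_n))
  ), class = "svr_tuning")
}

#' @export
print.svr_tuning <- function(x, ...) {
  cat(sprintf("PSO-tuned SVR: C = %.4f, gamma = %.4f (test RMSE %.5f, normalized)\n",
              x$best_C, x$best_gamma, x$objective_value))
  cat("train: "); print(x$train_metrics)
  cat("test:  "); print(x$test_metrics)
  cat("all:   "); print(x$all_metrics)
  invisible(x)
}

#' Search a fitted model for optimal extraction conditions
#'
#' Maximizes the model's raw-scale predicted yield over the actual-unit
#' factor box by particle swarm (expressed internally as minimizing the
#' negated prediction). Works for both model families: a quadratic
#' response surface (`rsm_model`) or a trained surrogate (`svr_model`
#' carrying normalization bounds).
#'
#' @param model An `rsm_model` or `svr_model`.
#' @param factors Factor definitions bounding the search box.
#' @param config A [pso_config()].
#' @param seed Seed for the swarm.
#' @param rounding Optional rounding specification passed to
#'   [round_practical()]; the default rounds to instrument-practical
#'   steps.
#' @return A list of class `optimization_outcome`: `conditions_actual`,
#'   `predicted_yield` (%), `conditions_practical`, `model_tag`,
#'   `pso_result`.
#' @export
optimize_conditions <- function(model, factors = NULL,
                                config = pso_config(), seed = NULL,
                                rounding = default_rounding_spec()) {
  if (inherits(model, "rsm_model")) {
    factors <- factors %||% model$factors
    tag <- "RSM"
    predfun <- function(x) predict(model, x)
  } else if (inherits(model, "svr_model")) {
    if (is.null(factors))
      stop("`factors` must be supplied for an SVR model", call. = FALSE)
    tag <- "PSO-SVR"
    predfun <- function(x) predict_svr(model, x, scale = "raw")
  } else stop("unsupported model class", call. = FALSE)
  lower <- vapply(factors, `[[`, 0, "low")
  upper <- vapply(factors, `[[`, 0, "high")
  pso <- pso_minimize(function(x) -predfun(x), lower, upper, config, seed)
  conditions <- setNames(pso$best_position, names(factors))
  structure(list(conditions_actual = conditions,
                 predicted_yield = -pso$best_value,
                 conditions_practical = round_practical(conditions, rounding),
                 model_tag = tag,
                 pso_result = pso),
            class = "optimization_outcome")
}

#' @export
print.optimization_outcome <- function(x, ...) {
  cat(sprintf("[%s] predicted maximum yield %.4f %%\n",
              x$model_tag, x$predicted_yield))
  cat("conditions:          "); print(round(x$conditions_actual, 4))
  cat("practical (rounded): "); print(x$conditions_practical)
  invisible(x)
}

#' Practical rounding of optimizer conditions
#'
#' Laboratory equipment cannot realize arbitrary settings; optimizer
#' output is therefore snapped to practical steps: time, ratio and
#' temperature to the nearest whole unit, power to the nearest 20 W
#' instrument step, and particle size to the nearest standard sieve
#' opening (0.25, 0.355, 0.425, 0.6, 0.85 mm).
#'
#' @param conditions Numeric 5-vector (time min, ratio mL/g, power W,
#'   temperature degC, particle size mm).
#' @param spec A rounding specification: list with numeric `steps` (per
#'   factor, `NA` for table lookup) and `sieve_mm` (allowed particle
#'   sizes).
#' @return Rounded 5-vector.
#' @examples
#' round_practical(c(34.2214, 18.8955, 178.2917, 41.3297, 0.3741))
#' @export
round_practical <- function(conditions, spec = default_rounding_spec()) {
  stopifnot(length(conditions) == length(spec$steps))
  out <- conditions
  for (i in seq_along(conditions)) {
    if (is.na(spec$steps[i])) {
      out[i] <- spec$sieve_mm[which.min(abs(spec$sieve_mm - conditions[i]))]
    } else {
      out[i] <- round(conditions[i] / spec$steps[i]) * spec$steps[i]
    }
  }
  out
}

#' @rdname round_practical
#' @export
default_rounding_spec <- function() {
  list(steps = c(1, 1, 20, 1, NA),
       sieve_mm = c(0.25, 0.355, 0.425, 0.6, 0.85))
}

#' Compare response-surface and surrogate predictions run by run
#'
#' For every evaluated run, records the observed yield and both models'
#' predictions and errors, fits the parity regression (prediction on
#' observation) for each model, and computes metric sets.
#'
#' @param rsm_model An `rsm_model`.
#' @param svr_model An `svr_model` with bounds.
#' @param table The [design_table()] holding the observations.
#' @param eval_ids Run ids to evaluate; default all runs.
#' @return A list of class `model_comparison`: `per_run` data frame,
#'   `parity` (slope/intercept/r2 per model), `metrics` per model.
#' @export
compare_models <- function(rsm_model, svr_model, table,
                           eval_ids = table$runs$run) {
  if (!length(eval_ids)) stop("empty evaluation set", call. = FALSE)
  rows <- rows_for_ids(table, eval_ids)
  if (anyNA(rows)) stop("unknown run ids in eval set", call. = FALSE)
  X <- design_actual(table)[rows, , drop = FALSE]
  y <- design_response(table)[rows]
  p_rsm <- predict(rsm_model, X)
  p_svr <- predict_svr(svr_model, X, scale = "raw")
  per_run <- data.frame(run = eval_ids, actual = y,
                        rsm_pred = p_rsm, svr_pred = p_svr,
                        rsm_error = p_rsm - y, svr_error = p_svr - y)
  parity_fit <- function(pred) {
    fit <- lm.fit(cbind(1, y), pred)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((pred - mean(pred))^2)
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         r2 = 1 - ss_res / ss_tot)
  }
  structure(list(
    per_run = per_run,
    parity = list(RSM = parity_fit(p_rsm), `PSO-SVR` = parity_fit(p_svr)),
    metrics = list(RSM = regression_metrics(y, p_rsm, "raw (%)"),
                   `PSO-SVR` = regression_metrics(y, p_svr, "raw (%)"))
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  for (m in names(x$parity)) {
    p <- x$parity[[m]]
    cat(sprintf("%s parity: pred = %.4f obs + %.4f (R2 %.4f);  ",
                m, p$slope, p$intercept, p$r2))
    print(x$metrics[[m]])
  }
  invisible(x)
}

#' Run the complete modeling workflow from a configuration
#'
#' Executes response-surface fit and ANOVA, PSO-SVR hyperparameter
#' tuning, condition optimization on both model families, and a model
#' comparison, writing JSON/CSV/text reports to an output directory.
#' For fixed seeds the workflow (and every report except file timestamps)
#' is fully reproducible.
#'
#' @param config Path to a YAML configuration, or an equivalent named
#'   list. Recognized fields: `design_csv` (path; default the bundled
#'   dataset), `out_dir` (default `"uaeopt_reports"`), `epsilon`,
#'   `split_ratio`, `split_seed`, `pso_seed`, `seeds` (vector of seeds
#'   for repeated tuning; overrides `split_seed`/`pso_seed` pairing),
#'   and `pso` (sub-list passed to [pso_config()]).
#' @return Invisibly, a list with every fitted object and the per-seed
#'   tuning summary.
#' @export
run_full <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("design_csv", "out_dir", "epsilon", "split_ratio",
             "split_seed", "pso_seed", "seeds", "pso")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  table <- if (!is.null(config$design_csv)) {
    if (!file.exists(config$design_csv))
      stop("design file not found: ", config$design_csv, call. = FALSE)
    read_design_csv(config$design_csv)
  } else rlmp_design()
  out_dir <- config$out_dir %||% "uaeopt_reports"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  epsilon <- config$epsilon %||% 0.01
  ratio <- config$split_ratio %||% 0.8
  pconf <- do.call(pso_config, config$pso %||% list())
  seeds <- config$seeds %||% (config$split_seed %||% 1)

  rsm <- fit_quadratic(table)
  anova <- rsm_anova(rsm, table)
  anova_json(anova, file.path(out_dir, "anova.json"))
  writeLines(anova_text(anova), file.path(out_dir, "anova.txt"))
  rsm_model_json(rsm, file.path(out_dir, "rsm_model.json"))

  tunings <- lapply(seeds, function(s) {
    split <- split_dataset(table, ratio, seed = s)
    tune_svr(table, split, config = pconf, epsilon = epsilon,
             seed = config$pso_seed %||% s)
  })
  all_r2 <- vapply(tunings, function(t) t$all_metrics$r2, 0)
  best_i <- which.max(all_r2)
  tuning <- tunings[[best_i]]
  tuning_summary <- data.frame(
    seed = unlist(seeds),
    best_C = vapply(tunings, `[[`, 0, "best_C"),
    best_gamma = vapply(tunings, `[[`, 0, "best_gamma"),
    test_rmse_norm = vapply(tunings, `[[`, 0, "objective_value"),
    all_r2 = all_r2)
  jsonlite::write_json(
    list(per_seed = tuning_summary,
         best = list(seed = tuning_summary$seed[best_i],
                     C = tuning$best_C, gamma = tuning$best_gamma,
                     all_r2 = all_r2[best_i]),
         median_all_r2 = stats::median(all_r2)),
    file.path(out_dir, "tuning.json"), auto_unbox = TRUE, digits = NA)
  svr_model_json(tuning$model, file.path(out_dir, "svr_model.json"))
  pso_result_json(tuning$pso_result, file.path(out_dir, "pso_history.json"))

  opt_rsm <- maximize_quadratic(rsm)
  opt_svr <- optimize_conditions(tuning$model, table$factors, pconf,
                                 seed = (config$pso_seed %||% seeds[[1]]))
  jsonlite::write_json(
    list(RSM = list(conditions = as.list(opt_rsm$conditions_actual),
                    practical = as.list(
                      round_practical(opt_rsm$conditions_actual)),
                    predicted_yield = opt_rsm$predicted_yield),
         `PSO-SVR` = list(conditions = as.list(opt_svr$conditions_actual),
                          practical = as.list(opt_svr$conditions_practical),
                          predicted_yield = opt_svr$predicted_yield)),
    file.path(out_dir, "optimum.json"), auto_unbox = TRUE, digits = NA)

  comparison <- compare_models(rsm, tuning$model, table)
  write.csv(comparison$per_run, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)

  invisible(list(table = table, rsm = rsm, anova = anova,
                 tunings = tunings, tuning = tuning,
                 tuning_summary = tuning_summary,
                 opt_rsm = opt_rsm, opt_svr = opt_svr,
                 comparison = comparison, out_dir = out_dir))
}
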