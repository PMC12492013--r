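# Synthetic data with known ground truth: Box-Behnken responses generated
# from a known second-order surface plus i.i.d. Gaussian noise, and
# 4-parameter logistic dose-response curves. Both are seeded and
# deterministic, so every downstream stage can be validated against the
# generating truth.

#' Specify a synthetic second-order response surface
#'
#' The default truth is the coded-unit refit of the bundled 46-run
#' extraction dataset with its residual standard deviation as the noise
#' level, so simulated designs statistically resemble that study.
#'
#' @param true_coefficients Named coefficient vector on the coded scale,
#'   in [expand_quadratic()] term order; default: the bundled-study
#'   refit.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian response
#'   noise, in percent yield (>= 0); default: the bundled-study residual
#'   standard deviation, `sqrt(0.0654)`.
#' @param n_center Number of center replicates.
#' @param factors Factor definitions.
#' @param seed Integer seed.
#' @return A list of class `surface_spec`.
#' @export
surface_spec <- function(true_coefficients = NULL, noise_sd = NULL,
                         n_center = 6, factors = rlmp_factors(),
                         seed = 1) {
  if (is.null(true_coefficients) || is.null(noise_sd)) {
    ref <- fit_quadratic(rlmp_design())
    true_coefficients <- true_coefficients %||% ref$coef_coded
    noise_sd <- noise_sd %||% sqrt(ref$mse)
  }
  terms <- quadratic_terms(names(factors))
  if (length(true_coefficients) != length(terms))
    stop("expected ", length(terms), " coefficients", call. = FALSE)
  if (is.null(names(true_coefficients)))
    names(true_coefficients) <- terms
  if (!identical(names(true_coefficients), terms))
    stop("coefficient names must follow the expand_quadratic() term order",
         call. = FALSE)
  stopifnot(noise_sd >= 0, n_center >= 1)
  structure(list(true_coefficients = true_coefficients,
                 noise_sd = noise_sd, n_center = as.integer(n_center),
                 factors = factors, seed = seed),
            class = "surface_spec")
}

#' Generate a Box-Behnken design with simulated responses
#'
#' Builds the design with [build_bbd()] and sets each response to the
#' quadratic surface value plus `Normal(0, noise_sd)` noise;
#' deterministic for a fixed spec seed. Simulated responses are floored
#' at zero (yields cannot be negative), which at the default noise level
#' never binds.
#'
#' @param spec A [surface_spec()].
#' @return A [design_table()] with responses.
#' @export
generate_design_response <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  table <- build_bbd(spec$factors, spec$n_center)
  M <- expand_quadratic(code_design(table))
  mean_y <- drop(M %*% spec$true_coefficients)
  y <- local_seed(spec$seed,
                  mean_y + rnorm(length(mean_y), 0, spec$noise_sd))
  design_table(spec$factors, design_actual(table),
               response = pmax(y, 0))
}

#' Generate a synthetic dose-response curve
#'
#' Four-parameter logistic mean plus i.i.d. Gaussian noise, seeded.
#'
#' @param bottom,top,ec50,hill 4PL parameters (see [logistic4()]).
#' @param doses Positive concentrations.
#' @param noise_sd Gaussian noise standard deviation (percent response).
#' @param seed Integer seed.
#' @return A data frame with columns `concentration` and `response`.
#' @export
generate_dose_response <- function(bottom, top, ec50, hill, doses,
                                   noise_sd = 0, seed = 1) {
  stopifnot(ec50 > 0, all(doses > 0), noise_sd >= 0)
  mean_r <- logistic4(doses, bottom, top, ec50, hill)
  r <- local_seed(seed, mean_r + rnorm(length(doses), 0, noise_sd))
  data.frame(concentration = doses, response = r)
}

#' Coefficient-recovery report for a fitted surface
#'
#' Compares a fitted model against the generating truth coefficient by
#' coefficient; a coefficient is `covered` when the estimate lies within
#' two standard errors of the truth (nominally ~95 % under Gaussian
#' noise).
#'
#' @param true_spec The [surface_spec()] the data were generated from.
#' @param model An `rsm_model` fitted to those data.
#' @return A data frame with columns `term`, `truth`, `estimate`, `se`,
#'   `covered`.
#' @export
recovery_report <- function(true_spec, model) {
  stopifnot(inherits(true_spec, "surface_spec"),
            inherits(model, "rsm_model"))
  if (!identical(names(true_spec$true_coefficients), model$term_order))
    stop("term order of the spec and the fitted model disagree",
         call. = FALSE)
  truth <- true_spec$true_coefficients
  est <- model$coef_coded
  se <- model$se_coded
  data.frame(term = model$term_order,
             truth = unname(truth), estimate = unname(est),
             se = unname(se),
             covered = unname(abs(est - truth) <= 2 * se))
}
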