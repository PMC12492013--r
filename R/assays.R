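# Assay arithmetic: linear calibration curves, extraction yield,
# radical-scavenging rate, and 4-parameter logistic IC50 estimation.

#' Linear calibration curve
#'
#' Absorbance as a linear function of analyte concentration:
#' `A = slope * C + intercept`.
#'
#' @param slope Absorbance per (mg/mL); must be non-zero.
#' @param intercept Absorbance at zero concentration.
#' @param analyte Analyte label.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, analyte = "analyte") {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (slope == 0) stop("calibration slope must be non-zero", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, analyte = analyte),
            class = "calibration_curve")
}

#' Bundled colorimetric calibration curves
#'
#' The phenol-sulfuric glucose curve (`A = 42.467 C + 0.0685`) used for
#' total-carbohydrate quantitation, and the Bradford bovine serum albumin
#' curve (`A = 0.0444 C - 0.042`) used for protein content.
#'
#' @return A `calibration_curve`.
#' @export
glucose_standard_curve <- function() {
  calibration_curve(42.467, 0.0685, "glucose (phenol-sulfuric)")
}

#' @rdname glucose_standard_curve
#' @export
bsa_standard_curve <- function() {
  calibration_curve(0.0444, -0.042, "BSA (Bradford)")
}

#' Invert a calibration curve
#'
#' @param absorbance Measured absorbance values.
#' @param curve A [calibration_curve()].
#' @return Concentrations, `(A - intercept) / slope`, in mg/mL.
#' @examples
#' invert_calibration(42.5355, glucose_standard_curve())  # 1.0
#' @export
invert_calibration <- function(absorbance, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Extraction yield from colorimetric quantitation
#'
#' `yield (%) = C * V * d / m * 100`, with the carbohydrate mass
#' `C * V * d` in milligrams converted to grams against the raw-material
#' mass `m` in grams.
#'
#' @param concentration Total carbohydrate concentration C, mg/mL.
#' @param volume Filtrate volume V, mL.
#' @param dilution Dilution factor d (dimensionless).
#' @param mass Raw-material mass m, g; must be positive.
#' @return Extraction yield in percent.
#' @examples
#' extraction_yield(0.5, 400, 10, 20)  # 10 %
#' @export
extraction_yield <- function(concentration, volume, dilution, mass) {
  stopifnot(all(concentration >= 0), all(volume > 0), all(dilution > 0))
  if (any(mass <= 0)) stop("raw-material mass must be positive",
                           call. = FALSE)
  (concentration * volume * dilution / 1000) / mass * 100
}

#' Radical-scavenging rate
#'
#' `R (%) = (1 - (A_s - A_b) / A_0) * 100`, where `A_s` is the
#' sample-plus-radical absorbance, `A_b` the sample blank, and `A_0` the
#' radical-only control.
#'
#' @param a_sample,a_blank,a_control Absorbance readings; the control
#'   must be positive.
#' @return Scavenging rate in percent.
#' @examples
#' scavenging_rate(0.52, 0.02, 1.0)  # 50 %
#' @export
scavenging_rate <- function(a_sample, a_blank, a_control) {
  if (any(a_control <= 0))
    stop("control absorbance must be positive", call. = FALSE)
  (1 - (a_sample - a_blank) / a_control) * 100
}

#' Four-parameter logistic response
#'
#' `f(x) = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`; increasing
#' in `x` for `hill > 0`, with `ec50` the concentration of half-maximal
#' response (midway between `bottom` and `top`).
#'
#' @param x Concentrations (> 0).
#' @param bottom,top Lower and upper asymptotes (percent response).
#' @param ec50 Midpoint concentration.
#' @param hill Hill slope.
#' @return Response values.
#' @export
logistic4 <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}

#' Estimate IC50 from a dose-response curve
#'
#' Fits a four-parameter logistic to (concentration, response) pairs by
#' Levenberg-Marquardt least squares and reports the IC50 as the
#' concentration at which the fitted curve crosses 50 % response. When
#' the logistic fit fails to converge, a monotone linear interpolation
#' between the two points bracketing 50 % is used instead (flagged in
#' the result). Responses slightly outside 0-100 are tolerated but
#' clipped at -5 and 105 with a warning.
#'
#' @param concentrations Positive concentrations, ug/mL.
#' @param responses Scavenging rates in percent.
#' @return A list of class `dose_response_fit`: `ic50` (`NA` when the
#'   responses never cross 50 %), `fit` (bottom/top/ec50/hill or `NULL`),
#'   `method` (`"4PL"` or `"interpolation"`), `defined`, plus the input
#'   data.
#' @examples
#' x <- c(2, 4, 8, 12, 16, 20, 25)
#' y <- logistic4(x, 0, 100, 10, 2)
#' estimate_ic50(x, y)$ic50  # 10
#' @export
estimate_ic50 <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 4)
    stop("need at least 4 points for a four-parameter fit", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be positive", call. = FALSE)
  o <- order(concentrations)
  x <- concentrations[o]; y <- responses[o]
  if (any(y < -5 | y > 105)) {
    warning("responses outside [-5, 105] clipped")
    y <- pmin(pmax(y, -5), 105)
  }
  crosses <- any(y < 50) && any(y > 50) || any(y == 50)
  out <- list(concentrations = x, responses = y, fit = NULL,
              ic50 = NA_real_, method = "4PL", defined = crosses)
  if (!crosses) {
    out$method <- "undefined"
    return(structure(out, class = "dose_response_fit"))
  }
  start <- list(bottom = max(min(y), -5), top = min(max(y), 105),
                lec50 = log(stats::approx(y, x, xout = 50, ties = mean)$y %||%
                              stats::median(x)),
                hill = 1)
  if (!is.finite(start$lec50)) start$lec50 <- log(stats::median(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (lec50 - log(x)))),
      start = start,
      lower = c(bottom = -5, top = 0, lec50 = log(min(x)) - 5,
                hill = 1e-3),
      upper = c(bottom = 100, top = 105, lec50 = log(max(x)) + 5,
                hill = 60),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ic50_from_fit <- function(cf) {
    bottom <- cf[["bottom"]]; top <- cf[["top"]]
    ec50 <- exp(cf[["lec50"]]); hill <- cf[["hill"]]
    if (!(bottom < 50 && top > 50)) return(NA_real_)
    # solve bottom + (top - bottom)/(1 + (ec50/c)^hill) = 50
    ratio <- (top - bottom) / (50 - bottom) - 1
    ec50 * ratio^(-1 / hill)
  }
  if (!is.null(fit)) {
    cf <- coef(fit)
    ic <- ic50_from_fit(cf)
    if (is.finite(ic)) {
      out$fit <- list(bottom = unname(cf[["bottom"]]),
                      top = unname(cf[["top"]]),
                      ec50 = unname(exp(cf[["lec50"]])),
                      hill = unname(cf[["hill"]]))
      out$ic50 <- ic
      return(structure(out, class = "dose_response_fit"))
    }
  }
  # fallback: monotone interpolation between the bracketing points
  out$method <- "interpolation"
  below <- which(y <= 50); above <- which(y >= 50)
  cand_i <- below[below < min(above)]
  i <- if (length(cand_i)) max(cand_i) else min(below)
  cand_j <- above[above > i]
  j <- if (length(cand_j)) min(cand_j) else max(above)
  if (y[j] == y[i]) out$ic50 <- x[i]
  else out$ic50 <- x[i] + (50 - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$defined) {
    cat("IC50 undefined: responses never cross 50 %\n")
  } else {
    cat(sprintf("IC50 %.4g ug/mL (%s)\n", x$ic50, x$method))
    if (!is.null(x$fit))
      cat(sprintf("4PL: bottom %.2f, top %.2f, ec50 %.4g, hill %.3f\n",
                  x$fit$bottom, x$fit$top, x$fit$ec50, x$fit$hill))
  }
  invisible(x)
}
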