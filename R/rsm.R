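# Second-order response-surface fitting and Design-Expert style ANOVA.
#
# All regression is done on coded units; actual-unit coefficients are
# obtained by algebraic substitution of the affine coding map, so the two
# coefficient sets describe the identical surface.

# Fixed 21-term ordering for 5 factors: intercept, linear, pairwise
# cross-products (lexicographic), squares.
quadratic_terms <- function(symbols) {
  k <- length(symbols)
  cross <- character()
  for (i in seq_len(k - 1))
    for (j in (i + 1):k)
      cross <- c(cross, paste0(symbols[i], ":", symbols[j]))
  c("(Intercept)", symbols, cross, paste0(symbols, "^2"))
}

#' Expand coded settings into the full second-order model matrix
#'
#' Columns are ordered: intercept, the k linear terms, the choose(k, 2)
#' pairwise cross-products in lexicographic order, then the k squares.
#'
#' @param coded An n-by-k numeric matrix of coded settings.
#' @return An n-by-(1 + 2k + choose(k, 2)) model matrix with named columns.
#' @examples
#' expand_quadratic(matrix(0, 1, 5))  # center point: (1, 0, ..., 0)
#' @export
expand_quadratic <- function(coded) {
  coded <- as.matrix(coded)
  if (!is.numeric(coded) || any(!is.finite(coded)))
    stop("coded settings must be finite numbers", call. = FALSE)
  n <- nrow(coded); k <- ncol(coded)
  if (k < 2) stop("need at least 2 factor columns", call. = FALSE)
  syms <- colnames(coded) %||% paste0("X", seq_len(k))
  p <- 1 + 2 * k + choose(k, 2)
  M <- matrix(NA_real_, n, p)
  M[, 1] <- 1
  M[, 1 + seq_len(k)] <- coded
  col <- 1 + k
  for (i in seq_len(k - 1))
    for (j in (i + 1):k) {
      col <- col + 1
      M[, col] <- coded[, i] * coded[, j]
    }
  M[, (col + 1):p] <- coded^2
  colnames(M) <- quadratic_terms(syms)
  M
}

#' Fit the full second-order polynomial to a design table
#'
#' Ordinary least squares of the response on the 21-term (for 5 factors)
#' quadratic expansion of the coded settings. The fit stores residuals,
#' hat-matrix leverages, the residual mean square, coefficient standard
#' errors, and the actual-unit coefficient set obtained by substituting
#' the coding map into the coded polynomial.
#'
#' @param table A [design_table()] whose runs all carry responses and
#'   whose expanded model matrix has full column rank.
#' @return An object of class `rsm_model`.
#' @examples
#' fit <- fit_quadratic(rlmp_design())
#' round(fit$mse, 4)
#' @export
fit_quadratic <- function(table) {
  stopifnot(inherits(table, "design_table"))
  y <- design_response(table)
  if (any(is.na(y)))
    stop("all runs must have responses to fit the surface", call. = FALSE)
  coded <- code_design(table)
  M <- expand_quadratic(coded)
  n <- nrow(M); p <- ncol(M)
  if (n <= p)
    stop("under-determined fit: ", n, " runs for ", p, " terms",
         call. = FALSE)
  qr_M <- qr(M)
  if (qr_M$rank < p)
    stop("model matrix is rank-deficient (rank ", qr_M$rank, " < ", p, ")",
         call. = FALSE)
  beta <- qr.coef(qr_M, y)
  fitted <- drop(M %*% beta)
  res <- y - fitted
  XtX_inv <- chol2inv(chol(crossprod(M)))
  h <- rowSums((M %*% XtX_inv) * M)
  mse <- sum(res^2) / (n - p)
  structure(list(
    term_order = colnames(M),
    coef_coded = setNames(beta, colnames(M)),
    coef_actual = to_actual_units(setNames(beta, colnames(M)), table$factors),
    residuals = res,
    fitted = fitted,
    leverage = h,
    mse = mse,
    se_coded = sqrt(mse * diag(XtX_inv)),
    XtX_inv = XtX_inv,
    model_matrix = M,
    response = y,
    n = n, p = p,
    factors = table$factors,
    response_name = table$response_name
  ), class = "rsm_model")
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("Second-order response surface: %d terms, %d runs\n",
              x$p, x$n))
  cat(sprintf("Residual MS %.4f on %d df\n", x$mse, x$n - x$p))
  cat("Coded coefficients:\n")
  print(round(x$coef_coded, 4))
  invisible(x)
}

#' Convert coded-unit coefficients to actual units
#'
#' Substitutes the affine coding map `z_i = (x_i - m_i) / s_i` (with
#' `m_i` the mid-range and `s_i` the half-range) into the coded
#' polynomial and collects terms, so that predictions from the two
#' coefficient sets are identical.
#'
#' @param coef_coded Named coefficient vector in the [expand_quadratic()]
#'   term order.
#' @param factors Named list of [factor_spec()] objects.
#' @return Coefficient vector in actual units, same term order.
#' @export
to_actual_units <- function(coef_coded, factors) {
  k <- length(factors)
  syms <- names(factors)
  terms <- quadratic_terms(syms)
  stopifnot(length(coef_coded) == length(terms))
  m <- vapply(factors, function(f) (f$low + f$high) / 2, 0)
  s <- vapply(factors, function(f) (f$high - f$low) / 2, 0)
  b <- setNames(as.numeric(coef_coded), terms)
  a <- setNames(numeric(length(terms)), terms)
  a["(Intercept)"] <- b["(Intercept)"]
  # linear terms: b_i * (x - m)/s
  for (i in seq_len(k)) {
    ti <- syms[i]
    a[ti] <- a[ti] + b[ti] / s[i]
    a["(Intercept)"] <- a["(Intercept)"] - b[ti] * m[i] / s[i]
  }
  # cross-products: b_ij (x_i - m_i)(x_j - m_j) / (s_i s_j)
  for (i in seq_len(k - 1))
    for (j in (i + 1):k) {
      tij <- paste0(syms[i], ":", syms[j])
      w <- b[tij] / (s[i] * s[j])
      a[tij] <- a[tij] + w
      a[syms[i]] <- a[syms[i]] - w * m[j]
      a[syms[j]] <- a[syms[j]] - w * m[i]
      a["(Intercept)"] <- a["(Intercept)"] + w * m[i] * m[j]
    }
  # squares: b_ii (x_i - m_i)^2 / s_i^2
  for (i in seq_len(k)) {
    tii <- paste0(syms[i], "^2")
    w <- b[tii] / s[i]^2
    a[tii] <- a[tii] + w
    a[syms[i]] <- a[syms[i]] - 2 * w * m[i]
    a["(Intercept)"] <- a["(Intercept)"] + w * m[i]^2
  }
  a
}

#' Predict from a fitted response surface
#'
#' @param object An `rsm_model`.
#' @param newdata Matrix (or vector) of points, one row per point.
#' @param scale Either `"actual"` (default) or `"coded"`, describing the
#'   units of `newdata`.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (percent).
#' @export
predict.rsm_model <- function(object, newdata, scale = c("actual", "coded"),
                              ...) {
  scale <- match.arg(scale)
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  if (any(!is.finite(newdata)))
    stop("prediction points must be finite", call. = FALSE)
  k <- length(object$factors)
  if (ncol(newdata) != k)
    stop("expected ", k, " factor columns", call. = FALSE)
  coded <- if (scale == "actual") {
    vapply(seq_len(k),
           function(j) code_value(object$factors[[j]], newdata[, j]),
           numeric(nrow(newdata)))
  } else newdata
  coded <- matrix(coded, ncol = k,
                  dimnames = list(NULL, names(object$factors)))
  if (any(abs(coded) > 1 + 1e-9))
    warning("predicting outside the coded cube [-1, +1]^k (extrapolation)")
  drop(expand_quadratic(coded) %*% object$coef_coded)
}

#' Design-Expert style ANOVA for a fitted response surface
#'
#' Produces the full variance decomposition: the overall model test,
#' per-term partial (Type III) sums of squares
#' `SS_j = b_j^2 / [(X'X)^-1]_jj` with F against the residual mean
#' square, the lack-of-fit test against pure error from replicated runs,
#' and the summary statistics R2, adjusted R2, PRESS-based predicted R2,
#' and adequacy precision (fitted-response range over the average
#' prediction standard error, `sqrt(p * MS_res / n)`).
#'
#' PRESS uses the leave-one-out identity `sum((e_i / (1 - h_ii))^2)`; no
#' refitting is performed. Without replicate runs the lack-of-fit rows are
#' omitted with a flag.
#'
#' @param model An `rsm_model` from [fit_quadratic()].
#' @param table The [design_table()] the model was fitted to (used to
#'   locate replicated center runs).
#' @return An object of class `rsm_anova`: list with `rows` (data frame
#'   of source/SS/df/MS/F/p) and a `summary` block.
#' @examples
#' fit <- fit_quadratic(rlmp_design())
#' a <- rsm_anova(fit, rlmp_design())
#' round(a$summary$r2, 3)
#' @export
rsm_anova <- function(model, table) {
  stopifnot(inherits(model, "rsm_model"), inherits(table, "design_table"))
  y <- model$response
  n <- model$n; p <- model$p
  ss_res <- sum(model$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1; df_res <- n - p
  ms_res <- model$mse
  f_mod <- (ss_mod / df_mod) / ms_res
  term_ss <- model$coef_coded^2 / diag(model$XtX_inv)

  rows <- data.frame(
    source = "Model", ss = ss_mod, df = df_mod, ms = ss_mod / df_mod,
    f = f_mod, p = pf(f_mod, df_mod, df_res, lower.tail = FALSE),
    stringsAsFactors = FALSE)
  for (term in model$term_order[-1]) {
    fj <- term_ss[term] / ms_res
    rows <- rbind(rows, data.frame(
      source = term, ss = term_ss[term], df = 1, ms = term_ss[term],
      f = fj, p = pf(fj, 1, df_res, lower.tail = FALSE)))
  }
  rows <- rbind(rows, data.frame(
    source = "Residual", ss = ss_res, df = df_res, ms = ms_res,
    f = NA_real_, p = NA_real_))

  # pure error from replicate groups (identical coded settings)
  coded <- code_design(table)
  key <- apply(round(coded, 9), 1, paste, collapse = "|")
  groups <- split(y, key)
  reps <- groups[vapply(groups, length, 0L) > 1]
  flags <- character()
  lof <- NULL
  if (length(reps) == 0) {
    flags <- c(flags, "no replicate runs: lack-of-fit not separable")
  } else {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), 0))
    df_pe <- sum(vapply(reps, function(g) length(g) - 1L, 0L))
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    ms_pe <- ss_pe / df_pe
    if (ms_pe <= 0) {
      flags <- c(flags, "zero pure-error mean square: lack-of-fit F undefined")
      f_lof <- NA_real_; p_lof <- NA_real_
    } else {
      f_lof <- (ss_lof / df_lof) / ms_pe
      p_lof <- pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    }
    rows <- rbind(rows,
      data.frame(source = "Lack of Fit", ss = ss_lof, df = df_lof,
                 ms = ss_lof / df_lof, f = f_lof, p = p_lof),
      data.frame(source = "Pure Error", ss = ss_pe, df = df_pe,
                 ms = ms_pe, f = NA_real_, p = NA_real_))
    lof <- list(f = f_lof, p = p_lof)
  }
  rows <- rbind(rows, data.frame(
    source = "Cor Total", ss = ss_tot, df = n - 1, ms = NA_real_,
    f = NA_real_, p = NA_real_))
  rownames(rows) <- NULL

  press <- sum((model$residuals / (1 - model$leverage))^2)
  summary <- list(
    r2 = 1 - ss_res / ss_tot,
    adj_r2 = 1 - ms_res / (ss_tot / (n - 1)),
    pred_r2 = 1 - press / ss_tot,
    press = press,
    adequacy_precision =
      (max(model$fitted) - min(model$fitted)) / sqrt(p * ms_res / n),
    model_f = f_mod,
    lack_of_fit = lof,
    n = n, p = p
  )
  structure(list(rows = rows, summary = summary, flags = flags),
            class = "rsm_anova")
}

format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "< 0.0001", sprintf("%.4f", p)))
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(anova_text(x), sep = "\n")
  invisible(x)
}

#' Render an ANOVA table as aligned plain text
#'
#' @param anova An `rsm_anova` object.
#' @return Character vector of lines.
#' @export
anova_text <- function(anova) {
  r <- anova$rows
  lines <- sprintf("%-14s %10s %4s %10s %8s %9s",
                   "Source", "SS", "df", "MS", "F", "p")
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "%-14s %10.4f %4d %10s %8s %9s",
      r$source[i], r$ss[i], r$df[i],
      ifelse(is.na(r$ms[i]), "", sprintf("%.4f", r$ms[i])),
      ifelse(is.na(r$f[i]), "", sprintf("%.2f", r$f[i])),
      format_p(r$p[i])))
  }
  s <- anova$summary
  lines <- c(lines, "",
             sprintf("R2 %.4f   Adjusted R2 %.4f   Predicted R2 %.4f",
                     s$r2, s$adj_r2, s$pred_r2),
             sprintf("PRESS %.4f   Adequacy precision %.4f",
                     s$press, s$adequacy_precision))
  if (length(anova$flags))
    lines <- c(lines, paste("note:", anova$flags))
  lines
}

#' Serialize an ANOVA table or fitted surface to JSON
#'
#' @param anova An `rsm_anova` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
anova_json <- function(anova, path = NULL) {
  x <- list(rows = anova$rows, summary = anova$summary[
    c("r2", "adj_r2", "pred_r2", "press", "adequacy_precision", "model_f")],
    flags = anova$flags)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname anova_json
#' @param model An `rsm_model`.
#' @export
rsm_model_json <- function(model, path = NULL) {
  x <- list(term_order = model$term_order,
            coef_coded = as.list(model$coef_coded),
            coef_actual = as.list(model$coef_actual),
            mse = model$mse,
            factors = lapply(model$factors, function(f)
              f[c("name", "symbol", "units", "low", "center", "high")]))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Maximize a fitted quadratic surface over a factor box
#'
#' Deterministic multistart bounded ascent (L-BFGS-B from the 2^k cube
#' corners, the center, and a fixed set of interior points), carried out
#' in coded units and reported in actual units. The surface itself is a
#' polynomial, so no seed dependence is introduced.
#'
#' @param model An `rsm_model`.
#' @param lower,upper Actual-unit bounds per factor; default to each
#'   factor's low/high design levels.
#' @param n_extra Number of additional deterministic interior starts.
#' @return A list of class `rsm_optimum`: `conditions_actual`,
#'   `conditions_coded`, `predicted_yield`.
#' @examples
#' opt <- maximize_quadratic(fit_quadratic(rlmp_design()))
#' round(opt$predicted_yield, 2)
#' @export
maximize_quadratic <- function(model, lower = NULL, upper = NULL,
                               n_extra = 16) {
  stopifnot(inherits(model, "rsm_model"))
  k <- length(model$factors)
  lower <- lower %||% vapply(model$factors, `[[`, 0, "low")
  upper <- upper %||% vapply(model$factors, `[[`, 0, "high")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("invalid optimization box", call. = FALSE)
  lo_c <- vapply(seq_len(k),
                 function(j) code_value(model$factors[[j]], lower[j]), 0)
  hi_c <- vapply(seq_len(k),
                 function(j) code_value(model$factors[[j]], upper[j]), 0)
  beta <- model$coef_coded
  negf <- function(z) -drop(expand_quadratic(matrix(z, 1, k)) %*% beta)
  grad <- function(z) {
    # analytic gradient of the quadratic in coded units
    syms <- names(model$factors)
    g <- numeric(k)
    for (i in seq_len(k)) {
      g[i] <- beta[syms[i]] + 2 * beta[paste0(syms[i], "^2")] * z[i]
      for (j in seq_len(k)) {
        if (j == i) next
        tn <- if (i < j) paste0(syms[i], ":", syms[j])
              else paste0(syms[j], ":", syms[i])
        g[i] <- g[i] + beta[tn] * z[j]
      }
    }
    -g
  }
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  starts <- sweep(sweep(corners, 2, hi_c - lo_c, "*"), 2, lo_c, "+")
  starts <- rbind(starts, (lo_c + hi_c) / 2)
  extra <- local_seed(8675309, matrix(runif(n_extra * k), n_extra, k))
  starts <- rbind(starts,
                  sweep(sweep(extra, 2, hi_c - lo_c, "*"), 2, lo_c, "+"))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- optim(starts[s, ], negf, gr = grad, method = "L-BFGS-B",
               lower = lo_c, upper = hi_c,
               control = list(factr = 10, pgtol = 1e-8))
    if (is.null(best) || o$value < best$value) best <- o
  }
  z <- pmin(pmax(best$par, lo_c), hi_c)
  actual <- vapply(seq_len(k),
                   function(j) decode_value(model$factors[[j]], z[j]), 0)
  structure(list(conditions_actual = setNames(actual, names(model$factors)),
                 conditions_coded = setNames(z, names(model$factors)),
                 predicted_yield = -best$value),
            class = "rsm_optimum")
}

#' @export
print.rsm_optimum <- function(x, ...) {
  cat("Surface maximum:", sprintf("%.4f %%\n", x$predicted_yield))
  print(round(x$conditions_actual, 4))
  invisible(x)
}
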