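#' Define an experimental factor with its coded levels
#'
#' A factor couples a physical quantity (name, units) with the three
#' settings used in a three-level design: `low`, `center` and `high`,
#' which map to coded levels -1, 0 and +1. The center is not required to
#' be the arithmetic midpoint of low and high, although it is for all
#' factors of the bundled extraction study.
#'
#' @param name Human-readable factor name, e.g. `"Ultrasound time"`.
#' @param symbol Short symbol, `"X1"` ... `"X5"` for a five-factor design.
#' @param units Physical units as text, e.g. `"min"`.
#' @param low,center,high Factor settings in actual units; must be strictly
#'   increasing.
#' @param csv_name Column name used for this factor in the canonical CSV
#'   dialect; defaults to the symbol.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("Ultrasound time", "X1", "min", 20, 30, 40)
#' @export
factor_spec <- function(name, symbol, units, low, center, high,
                        csv_name = symbol) {
  stopifnot(is.character(name), is.character(symbol), is.character(units))
  vals <- c(low = low, center = center, high = high)
  if (any(!is.finite(vals)))
    stop("factor levels must be finite numbers", call. = FALSE)
  if (!(low < center && center < high))
    stop("factor '", name, "': levels must satisfy low < center < high",
         call. = FALSE)
  structure(list(name = name, symbol = symbol, units = units,
                 low = low, center = center, high = high,
                 csv_name = csv_name),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("%s (%s, %s): %-g / %g / %g  [coded -1 / 0 / +1]\n",
              x$name, x$symbol, x$units, x$low, x$center, x$high))
  invisible(x)
}

#' Factor definitions of the bundled ultrasound-extraction study
#'
#' The five factors and levels of the bundled Box-Behnken extraction
#' dataset: ultrasound time 20/30/40 min, liquid-solid ratio 15/20/25
#' mL/g, ultrasonic power 160/180/200 W, temperature 30/40/50 degC, and
#' raw-material particle size 0.25/0.55/0.85 mm.
#'
#' @return A named list of five [factor_spec()] objects (`X1` ... `X5`).
#' @seealso [rlmp_design()] for the accompanying 46-run design table.
#' @export
rlmp_factors <- function() {
  specs <- list(
    factor_spec("Ultrasound time",        "X1", "min",   20,   30,   40,
                "X1_time_min"),
    factor_spec("Liquid-solid ratio",     "X2", "mL/g",  15,   20,   25,
                "X2_ratio_mL_g"),
    factor_spec("Ultrasonic power",       "X3", "W",     160,  180,  200,
                "X3_power_W"),
    factor_spec("Ultrasonic temperature", "X4", "degC",  30,   40,   50,
                "X4_temp_C"),
    factor_spec("Particle size",          "X5", "mm",    0.25, 0.55, 0.85,
                "X5_particle_mm")
  )
  setNames(specs, vapply(specs, `[[`, "", "symbol"))
}

#' Map between actual and coded factor levels
#'
#' The standard affine coding sends the midpoint of `low` and `high` to 0
#' and the half-range to 1: `coded = 2 (actual - (low + high)/2) /
#' (high - low)`. `decode_value()` is its exact inverse.
#'
#' @param spec A [factor_spec()].
#' @param actual,coded Numeric vector of settings.
#' @return Numeric vector of the transformed settings.
#' @examples
#' tf <- rlmp_factors()$X1
#' code_value(tf, 40)     # +1
#' decode_value(tf, 0.5)  # 35
#' @export
code_value <- function(spec, actual) {
  stopifnot(inherits(spec, "factor_spec"))
  if (any(!is.finite(actual))) stop("non-finite actual value", call. = FALSE)
  2 * (actual - (spec$low + spec$high) / 2) / (spec$high - spec$low)
}

#' @rdname code_value
#' @export
decode_value <- function(spec, coded) {
  stopifnot(inherits(spec, "factor_spec"))
  if (any(!is.finite(coded))) stop("non-finite coded value", call. = FALSE)
  (spec$low + spec$high) / 2 + coded * (spec$high - spec$low) / 2
}

#' Construct a design table
#'
#' A design table holds the factor definitions, the run settings in actual
#' units, and (optionally) the measured response for each run.
#'
#' @param factors Named list of [factor_spec()] objects.
#' @param actual Matrix or data frame of run settings, one column per
#'   factor in the order of `factors`.
#' @param response Optional numeric vector of responses (percent yield);
#'   `NA` marks unexecuted runs.
#' @param run_id Optional integer run identifiers; defaults to `1:n`.
#' @param response_name Label for the response column.
#' @return An object of class `design_table`.
#' @export
design_table <- function(factors, actual, response = NULL, run_id = NULL,
                         response_name = "extraction yield (%)") {
  stopifnot(is.list(factors), length(factors) >= 1,
            all(vapply(factors, inherits, TRUE, "factor_spec")))
  actual <- as.matrix(actual)
  k <- length(factors)
  if (ncol(actual) != k)
    stop("`actual` must have one column per factor (", k, ")", call. = FALSE)
  n <- nrow(actual)
  if (!is.numeric(actual) || any(!is.finite(actual)))
    stop("run settings must be finite numbers", call. = FALSE)
  run_id <- run_id %||% seq_len(n)
  if (anyDuplicated(run_id))
    stop("duplicate run ids: ",
         paste(unique(run_id[duplicated(run_id)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(response)) {
    stopifnot(length(response) == n)
    ok <- is.na(response) | (is.finite(response) & response >= 0)
    if (!all(ok))
      stop("responses must be finite and non-negative", call. = FALSE)
  } else {
    response <- rep(NA_real_, n)
  }
  syms <- vapply(factors, `[[`, "", "symbol")
  runs <- data.frame(run = as.integer(run_id), actual, response)
  names(runs) <- c("run", syms, "response")
  structure(list(factors = setNames(factors, syms), runs = runs,
                 response_name = response_name),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  nr <- sum(!is.na(x$runs$response))
  cat(sprintf("Design table: %d factors, %d runs (%d with %s), %d center runs\n",
              length(x$factors), nrow(x$runs), nr, x$response_name,
              sum(is_center_run(x))))
  print(utils::head(x$runs, 6))
  if (nrow(x$runs) > 6) cat("...\n")
  invisible(x)
}

#' Coded settings of a design table
#'
#' @param table A [design_table()].
#' @return An n-by-k matrix of coded levels, columns named by factor symbol.
#' @export
code_design <- function(table) {
  stopifnot(inherits(table, "design_table"))
  syms <- names(table$factors)
  out <- vapply(syms,
                function(s) code_value(table$factors[[s]], table$runs[[s]]),
                numeric(nrow(table$runs)))
  out <- matrix(out, nrow = nrow(table$runs),
                dimnames = list(NULL, syms))
  out
}

#' Identify center runs (all factors at their coded 0)
#'
#' @param table A [design_table()].
#' @param tol Absolute tolerance in coded units.
#' @return Logical vector over runs.
#' @export
is_center_run <- function(table, tol = 1e-9) {
  coded <- code_design(table)
  apply(abs(coded) < tol, 1, all)
}

#' Responses of a design table
#'
#' @param table A [design_table()].
#' @return Numeric vector of responses (`NA` where absent).
#' @export
design_response <- function(table) table$runs$response

#' Actual-unit settings of a design table
#'
#' @param table A [design_table()].
#' @return An n-by-k numeric matrix.
#' @export
design_actual <- function(table) {
  as.matrix(table$runs[names(table$factors)])
}

#' Build a Box-Behnken design
#'
#' For k factors, the design consists of the 4 * choose(k, 2) edge
#' midpoints -- every (+-1, +-1) combination over each factor pair with the
#' remaining factors at 0 -- plus `n_center` replicated center runs. For
#' the five-factor case this gives 40 + n_center runs. Generated runs are
#' ordered pair-lexicographically with centers last; responses are absent.
#'
#' @param factors Named list of at least three [factor_spec()] objects.
#' @param n_center Number of center replicates (>= 1).
#' @return A [design_table()] with empty responses.
#' @examples
#' nrow(build_bbd(rlmp_factors(), 6)$runs)  # 46
#' @export
build_bbd <- function(factors, n_center) {
  k <- length(factors)
  if (k < 3) stop("a Box-Behnken design needs at least 3 factors",
                  call. = FALSE)
  stopifnot(n_center >= 1)
  pairs <- utils::combn(k, 2)
  edge <- matrix(0, 4 * ncol(pairs), k)
  lv <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))[, 2:1]  # (-,-),(-,+),(+,-),(+,+)
  for (p in seq_len(ncol(pairs))) {
    rows <- (p - 1) * 4 + 1:4
    edge[rows, pairs[1, p]] <- lv[, 1]
    edge[rows, pairs[2, p]] <- lv[, 2]
  }
  coded <- rbind(edge, matrix(0, n_center, k))
  actual <- vapply(seq_len(k),
                   function(j) decode_value(factors[[j]], coded[, j]),
                   numeric(nrow(coded)))
  design_table(factors, actual)
}

#' Validate a design table as a Box-Behnken design
#'
#' Report-style validation: duplicate run identifiers and coded settings
#' outside the coded range -1..+1 fail the design; missing responses and the center-run
#' count are reported as informational messages.
#'
#' @param table A [design_table()].
#' @return A list of class `bbd_validation` with elements `pass`,
#'   `messages`, `n_center` and `n_runs`.
#' @export
validate_bbd <- function(table) {
  stopifnot(inherits(table, "design_table"))
  msgs <- character()
  pass <- TRUE
  n <- nrow(table$runs)
  if (n == 0) {
    return(structure(list(pass = FALSE, messages = "design has no runs",
                          n_center = 0L, n_runs = 0L),
                     class = "bbd_validation"))
  }
  dup <- unique(table$runs$run[duplicated(table$runs$run)])
  if (length(dup)) {
    pass <- FALSE
    msgs <- c(msgs, paste0("duplicate run ids: ", paste(dup, collapse = ", ")))
  }
  coded <- code_design(table)
  out_of_range <- which(apply(abs(coded) > 1 + 1e-9, 1, any))
  if (length(out_of_range)) {
    pass <- FALSE
    msgs <- c(msgs, paste0("coded settings outside [-1, +1] in runs: ",
                           paste(table$runs$run[out_of_range], collapse = ", ")))
  }
  n_missing <- sum(is.na(table$runs$response))
  if (n_missing > 0)
    msgs <- c(msgs, paste0(n_missing, " runs without responses"))
  n_center <- sum(is_center_run(table))
  msgs <- c(msgs, paste0(n_center, " center runs"))
  structure(list(pass = pass, messages = msgs,
                 n_center = as.integer(n_center), n_runs = as.integer(n)),
            class = "bbd_validation")
}

#' @export
print.bbd_validation <- function(x, ...) {
  cat(if (x$pass) "PASS" else "FAIL",
      sprintf("(%d runs, %d center)\n", x$n_runs, x$n_center))
  for (m in x$messages) cat(" -", m, "\n")
  invisible(x)
}

#' Read and write design tables in the canonical CSV dialect
#'
#' The canonical dialect has a `run` column, one actual-unit column per
#' factor named by the factor's `csv_name`, and an optional `yield_pct`
#' response column; period decimal separator, UTF-8.
#'
#' @param path File path.
#' @param factors Factor definitions expected in the file; defaults to the
#'   bundled study's five factors.
#' @return `read_design_csv()` returns a [design_table()];
#'   `write_design_csv()` invisibly returns `path`.
#' @export
read_design_csv <- function(path, factors = rlmp_factors()) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  need <- c("run", vapply(factors, `[[`, "", "csv_name"))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("design CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cn in intersect(c(need, "yield_pct"), names(df))) {
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "'", call. = FALSE)
  }
  if (anyDuplicated(df$run))
    stop("duplicate run ids in CSV: ",
         paste(unique(df$run[duplicated(df$run)]), collapse = ", "),
         call. = FALSE)
  response <- if ("yield_pct" %in% names(df)) df$yield_pct else NULL
  design_table(factors,
               as.matrix(df[vapply(factors, `[[`, "", "csv_name")]),
               response = response, run_id = df$run)
}

#' @rdname read_design_csv
#' @param table A [design_table()] to serialize.
#' @export
write_design_csv <- function(table, path) {
  stopifnot(inherits(table, "design_table"))
  df <- table$runs
  names(df) <- c("run", vapply(table$factors, `[[`, "", "csv_name"),
                 "yield_pct")
  if (all(is.na(df$yield_pct))) df$yield_pct <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 46-run Box-Behnken extraction dataset
#'
#' The complete five-factor Box-Behnken design and measured polysaccharide
#' extraction yields of the bundled ultrasound-extraction study (46 runs,
#' of which 6 are center replicates), in actual units.
#'
#' @return A [design_table()] with 46 runs and yields in percent.
#' @seealso [rlmp_factors()]
#' @export
rlmp_design <- function() {
  path <- system.file("extdata", "rlmp_bbd_design.csv", package = "uaeopt",
                      mustWork = TRUE)
  read_design_csv(path)
}

#' Serialize factor definitions to and from YAML
#'
#' @param factors Named list of [factor_spec()] objects.
#' @param path File path.
#' @return `factors_to_yaml()` invisibly returns `path`;
#'   `factors_from_yaml()` returns the factor list.
#' @export
factors_to_yaml <- function(factors, path) {
  x <- lapply(factors, function(f)
    f[c("name", "symbol", "units", "low", "center", "high", "csv_name")])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname factors_to_yaml
#' @export
factors_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  specs <- lapply(x, function(f)
    factor_spec(f$name, f$symbol, f$units, f$low, f$center, f$high,
                f$csv_name %||% f$symbol))
  setNames(specs, vapply(specs, `[[`, "", "symbol"))
}
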