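# Robust standardization of assessment variables and similarity weights.
#
# Before distance estimation every assessment variable is z-standardized so
# no variable dominates merely through its units. The standardization
# moments are fitted robustly: values outside the Tukey fences
# (Q1 - k*IQR, Q3 + k*IQR) are excluded from the mean/sd fit so gross
# outliers do not bias it — the outlying values themselves are still
# standardized and kept downstream.

#' Tukey fences of a sample
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param k Fence multiplier (default 1.5).
#' @return Numeric `c(lower, upper)` = `c(Q1 - k*IQR, Q3 + k*IQR)` with
#'   linear-interpolation quartiles.
#' @examples
#' tukey_fences(c(1, 2, 3, 4, 100))  # c(-1, 7)
#' @export
tukey_fences <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    abort_data("tukey_fences needs at least 4 finite values")
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Fit a robust standardization model on baseline values
#'
#' Per variable, computes Tukey fences, then the mean and sample standard
#' deviation of the in-fence values only. Variables whose clean subset has
#' (near-)zero spread are flagged degenerate; they standardize to 0 and are
#' excluded from participant distances.
#'
#' @param baseline Tibble/data frame of baseline assessment values, one
#'   column per variable (non-variable columns `participant_id`/`timepoint`
#'   are ignored).
#' @param k Tukey fence multiplier (default 1.5).
#' @return A tibble of class `standardization_model`: `variable`, `mean`,
#'   `sd`, `lower`, `upper`, `n_used`, `degenerate`.
#' @export
fit_standardization <- function(baseline, k = 1.5) {
  vars <- setdiff(names(baseline), c("participant_id", "timepoint"))
  if (length(vars) == 0) abort_data("no variables to standardize")
  rows <- lapply(vars, function(v) {
    x <- baseline[[v]]
    x <- x[is.finite(x)]
    if (length(x) < 4)
      abort_data(paste0("variable '", v,
                        "' has fewer than 4 finite baseline values"))
    f <- tukey_fences(x, k = k)
    clean <- x[x >= f[1] & x <= f[2]]
    if (length(clean) == 0) clean <- x  # unreachable for k >= 0; guard anyway
    m <- mean(clean)
    s <- if (length(clean) > 1) stats::sd(clean) else 0
    degenerate <- !is.finite(s) || s < .Machine$double.eps^0.5
    tibble::tibble(variable = v, mean = m,
                   sd = if (degenerate) NA_real_ else s,
                   lower = unname(f[1]), upper = unname(f[2]),
                   n_used = length(clean), degenerate = degenerate)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("standardization_model", class(out))
  out
}

#' Standardize values with a fitted model
#'
#' `z = (x - mean) / sd` with the robustly fitted moments. Degenerate
#' variables map to 0 with a warning. Outlying values are standardized like
#' any other (only the fit excluded them).
#'
#' @param model A `standardization_model`.
#' @param variable Variable id.
#' @param x Numeric vector of raw values.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(model, variable, x) {
  row <- model[model$variable == variable, ]
  if (nrow(row) == 0)
    abort_data(paste0("unknown variable '", variable, "' in model"))
  if (row$degenerate) {
    warning("variable '", variable,
            "' is degenerate (zero spread); standardizing to 0",
            call. = FALSE)
    return(ifelse(is.na(x), NA_real_, 0))
  }
  (x - row$mean) / row$sd
}

#' Resolve the five-level weight vocabulary to numeric variable weights
#'
#' A dimension-level importance label applies to all of that dimension's
#' variables unless a per-variable override is given. Labels map to
#' weights: very low = 0, low = 0.5, medium = 1, high = 1.5, very high = 2.
#'
#' @param config A list with elements `dimensions` (named character vector
#'   of level labels per coaching dimension; unnamed dimensions default to
#'   `"medium"`) and optionally `variables` (named character vector of
#'   per-variable override labels).
#' @param variable_specs Assessment-variable specification tibble.
#' @return Named numeric weight vector, one entry per variable id.
#' @examples
#' resolve_weights(
#'   list(dimensions = c(Physical = "low", Cognitive = "high",
#'                       Nutritional = "high")),
#'   default_variable_specs())
#' @export
resolve_weights <- function(config = list(), variable_specs = default_variable_specs()) {
  dims <- config$dimensions %||% character()
  overrides <- config$variables %||% character()
  check_levels <- function(x) {
    bad <- setdiff(unique(unname(x)), names(WEIGHT_LEVELS))
    if (length(bad) > 0)
      abort_data(paste0("unknown weight level(s): ",
                        paste0("'", bad, "'", collapse = ", ")))
  }
  check_levels(dims); check_levels(overrides)
  bad_dim <- setdiff(names(dims), COACH_DIMENSIONS)
  if (length(bad_dim) > 0)
    abort_data(paste0("unknown dimension(s) in weight config: ",
                      paste(bad_dim, collapse = ", ")))
  bad_var <- setdiff(names(overrides), variable_specs$id)
  if (length(bad_var) > 0)
    abort_data(paste0("unknown variable(s) in weight config: ",
                      paste(bad_var, collapse = ", ")))

  level_of_dim <- function(d) if (d %in% names(dims)) dims[[d]] else "medium"
  w <- vapply(seq_len(nrow(variable_specs)), function(i) {
    v <- variable_specs$id[i]
    lvl <- if (v %in% names(overrides)) overrides[[v]]
           else level_of_dim(variable_specs$dimension[i])
    WEIGHT_LEVELS[[lvl]]
  }, numeric(1))
  stats::setNames(w, variable_specs$id)
}

#' Export a standardization model as JSON
#' @param model A `standardization_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standardization_json <- function(model, path) {
  jsonlite::write_json(tibble::as_tibble(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Import a standardization model from JSON
#' @param path JSON file written by [write_standardization_json()].
#' @return A `standardization_model`.
#' @export
read_standardization_json <- function(path) {
  df <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  df$sd[!is.finite(df$sd)] <- NA_real_
  class(df) <- c("standardization_model", class(df))
  df
}
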