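# Pre/post improvement estimation and activity-trajectory views.
#
# A participant's improvement in a coaching dimension is the mean, over that
# dimension's assessment variables, of the orientation-corrected change in
# standardized score between the two timepoints:
#
#   change(dim) = mean_i  orientation_i * (z_final_i - z_baseline_i).
#
# Changes are color-coded: improved (green) / same (yellow) / worsened
# (red), with a shade in [0, 1] proportional to |change| relative to the
# cohort's largest |change| in that dimension.

#' Orientation-corrected standardized improvement in one dimension
#'
#' @param baseline,final One-row assessment records (tibbles with one column
#'   per variable id) for the same participant.
#' @param model A `standardization_model` fitted on baseline values.
#' @param specs Assessment-variable specification tibble.
#' @param dimension Coaching dimension.
#' @return Signed change (positive = improved), the mean over the
#'   dimension's non-degenerate variables observed at both timepoints.
#' @export
improvement <- function(baseline, final, model,
                        specs = default_variable_specs(), dimension) {
  vars <- specs$id[specs$dimension == dimension]
  vars <- intersect(vars, model$variable[!model$degenerate])
  vars <- intersect(vars, intersect(names(baseline), names(final)))
  changes <- vapply(vars, function(v) {
    zb <- standardize(model, v, baseline[[v]])
    zf <- standardize(model, v, final[[v]])
    specs$orientation[specs$id == v] * (zf - zb)
  }, numeric(1))
  changes <- changes[!is.na(changes)]
  if (length(changes) == 0)
    abort_data(paste0("no usable variables for dimension '", dimension, "'"))
  mean(changes)
}

#' Improvement profiles for a whole cohort
#'
#' Computes the per-participant, per-dimension improvement for every
#' participant with both assessments, then categorizes each change with
#' [categorize()] using the dimension-wise cohort maximum |change|.
#'
#' @param dataset A `cohort_dataset`.
#' @param model A `standardization_model` (default: fitted on baseline).
#' @param eps Half-width of the "remained in the same state" band in
#'   standardized units (default 0.1).
#' @param dimensions Dimensions to profile (default: the dimensions that
#'   have assessment variables).
#' @return Tibble of class `improvement_profiles`: `participant_id`,
#'   `dimension`, `change`, `category`, `shade`.
#' @export
improvement_profiles <- function(dataset, model = NULL, eps = 0.1,
                                 dimensions = NULL) {
  a <- dataset$assessments
  base <- a[a$timepoint == "baseline", ]
  fin <- a[a$timepoint == "final", ]
  if (is.null(model)) model <- fit_standardization(base)
  if (is.null(dimensions))
    dimensions <- intersect(COACH_DIMENSIONS,
                            unique(dataset$variable_specs$dimension))
  ids <- intersect(base$participant_id, fin$participant_id)
  if (length(ids) == 0) abort_data("no participants with both assessments")
  rows <- list()
  for (dim in dimensions) {
    ch <- vapply(ids, function(p) {
      improvement(base[base$participant_id == p, ],
                  fin[fin$participant_id == p, ],
                  model, dataset$variable_specs, dim)
    }, numeric(1))
    max_abs <- max(abs(ch))
    cat_shade <- categorize(ch, eps = eps, max_abs = max_abs)
    rows[[dim]] <- tibble::tibble(participant_id = ids, dimension = dim,
                                  change = unname(ch),
                                  category = unname(cat_shade$category),
                                  shade = unname(cat_shade$shade))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("improvement_profiles", class(out))
  out
}

#' Categorize a change value with a color shade
#'
#' Changes within `eps` of zero are "same" (yellow, shade 0); otherwise the
#' sign selects "improved" (green) or "worsened" (red) and the shade is
#' `|change| / max_abs`, the magnitude relative to the cohort maximum.
#'
#' @param change Numeric vector of signed changes.
#' @param eps Tolerance band half-width (>= 0).
#' @param max_abs Cohort maximum |change| (used as the shade denominator).
#' @return List with `category` (character vector) and `shade` (numeric in
#'   [0, 1]).
#' @export
categorize <- function(change, eps = 0.1, max_abs = max(abs(change))) {
  stopifnot(eps >= 0)
  category <- ifelse(abs(change) <= eps, "same",
                     ifelse(change > 0, "improved", "worsened"))
  shade <- ifelse(category == "same", 0,
                  if (max_abs > 0) abs(change) / max_abs else 0)
  list(category = category, shade = pmin(shade, 1))
}

#' Moving-window smoothing of a daily series
#'
#' Applies a centered moving window of `n` days with statistic `mean`,
#' `max` or `min`. The window shrinks at the series boundaries; missing
#' days are excluded from the window statistic, and a window with no
#' observed day yields `NA`.
#'
#' @param series Numeric vector (may contain `NA` for missing days).
#' @param n Odd positive window length.
#' @param method `"mean"`, `"max"` or `"min"`.
#' @return Smoothed numeric vector, same length as `series`.
#' @examples
#' smooth_series(c(1, 2, 3, 4, 5), 3, "mean")  # 1.5 2 3 4 4.5
#' @export
smooth_series <- function(series, n, method = c("mean", "max", "min")) {
  method <- match.arg(method)
  if (length(n) != 1 || !is.finite(n) || n < 1 || n %% 2 != 1)
    abort_data("smoothing window n must be an odd positive integer")
  half <- (n - 1) / 2
  len <- length(series)
  stat <- switch(method, mean = mean, max = max, min = min)
  vapply(seq_len(len), function(i) {
    w <- series[max(1, i - half):min(len, i + half)]
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_real_ else stat(w)
  }, numeric(1))
}

#' Smoothed, improvement-colored activity trajectories of a group
#'
#' For every member of the selected cluster (or of the whole cohort), the
#' daily activity series of one dimension is smoothed with a centered
#' moving window, and colored by the member's improvement in a (possibly
#' different) dimension.
#'
#' @param clustering A `flat_clustering`, or `NULL` for the whole cohort.
#' @param matrix An `activity_matrix`.
#' @param activity_dim Dimension whose daily activity is shown.
#' @param color_dim Dimension whose improvement drives the color.
#' @param profiles An `improvement_profiles` tibble.
#' @param group Cluster id to show, or `"all"` for the entire cohort.
#' @param n Odd smoothing window (default 7).
#' @param method Smoothing statistic (default `"mean"`).
#' @return Tibble of class `trajectory_view`: `participant_id`,
#'   `day_index`, `value`, `category`, `shade`, with attributes recording
#'   the view parameters.
#' @export
group_trajectories <- function(clustering, matrix, activity_dim, color_dim,
                               profiles, group = "all", n = 7,
                               method = "mean") {
  if (identical(group, "all") || is.null(clustering)) {
    members <- unique(matrix$participant_id)
  } else {
    lab <- clustering$labels
    if (!group %in% lab$cluster)
      abort_data(paste0("unknown group '", group, "'"))
    members <- lab$participant_id[lab$cluster == group]
  }
  prof <- profiles[profiles$dimension == color_dim, ]
  n_days <- attr(matrix, "n_days") %||% (max(matrix$day_index) + 1L)
  rows <- lapply(members, function(p) {
    if (!p %in% matrix$participant_id) return(NULL)
    s <- smooth_series(activity_series(matrix, p, activity_dim,
                                       n_days = n_days), n, method)
    pr <- prof[prof$participant_id == p, ]
    tibble::tibble(participant_id = p, day_index = seq_len(n_days) - 1L,
                   value = s,
                   category = if (nrow(pr) > 0) pr$category else NA_character_,
                   shade = if (nrow(pr) > 0) pr$shade else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "activity_dim") <- activity_dim
  attr(out, "color_dim") <- color_dim
  attr(out, "group") <- group
  attr(out, "window") <- n
  attr(out, "method") <- method
  class(out) <- c("trajectory_view", class(out))
  out
}

#' Filter participants by per-dimension change ranges
#'
#' Parallel-coordinate range brushing: keeps the participants whose change
#' lies inside every specified closed interval.
#'
#' @param profiles An `improvement_profiles` tibble.
#' @param ranges Named list of `c(lower, upper)` intervals per dimension;
#'   dimensions without an entry are unconstrained.
#' @return Character vector of participant ids matching all intervals.
#' @export
filter_by_ranges <- function(profiles, ranges = list()) {
  ids <- unique(profiles$participant_id)
  if (length(ranges) == 0) return(ids)
  bad <- setdiff(names(ranges), COACH_DIMENSIONS)
  if (length(bad) > 0)
    abort_data(paste0("unknown dimension(s) in range filter: ",
                      paste(bad, collapse = ", ")))
  for (dim in names(ranges)) {
    iv <- ranges[[dim]]
    if (length(iv) != 2 || is.na(iv[1]) || is.na(iv[2]) || iv[1] > iv[2])
      abort_data(paste0("invalid interval for dimension '", dim, "'"))
    pr <- profiles[profiles$dimension == dim, ]
    keep <- pr$participant_id[pr$change >= iv[1] & pr$change <= iv[2]]
    ids <- intersect(ids, keep)
  }
  ids
}

#' Export improvement profiles as CSV
#' @param profiles An `improvement_profiles` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  readr::write_csv(tibble::as_tibble(profiles), path, progress = FALSE)
  invisible(path)
}
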