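# Daily per-dimension activity scoring.
#
# The daily activity level of a coaching dimension is the weighted sum of
# the encoded answer indices of the dimension's questions,
#
#   activity(day, dim) = sum_i w_i * a_i ,
#
# where thrice-daily questions contribute one term per administration slot.
# Missing answers contribute 0 and lower the cell's completeness (the
# fraction of expected answer slots actually answered).

# expected answer slots per dimension = sum of administrations over its rows
expected_slots <- function(question_specs) {
  stats::aggregate(administrations ~ dimension, question_specs, sum)
}

#' Build the participant x day x dimension activity matrix
#'
#' Computes the daily weighted-sum activity level of every dimension for
#' every participant-day with at least one recorded answer. Days without
#' any record are absent (treated as missing downstream).
#'
#' @param dataset A `cohort_dataset`.
#' @param completeness_floor Drop cells whose completeness is strictly below
#'   this fraction (default 0: keep everything).
#' @return A tibble of class `activity_matrix`: `participant_id`,
#'   `day_index`, `dimension`, `value`, `completeness`, with the study
#'   window length in attribute `n_days`.
#' @export
build_activity_matrix <- function(dataset, completeness_floor = 0) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  qs <- dataset$question_specs
  daily <- dataset$daily

  if (nrow(daily) == 0) {
    out <- tibble::tibble(participant_id = character(), day_index = integer(),
                          dimension = character(), value = numeric(),
                          completeness = numeric())
    attr(out, "n_days") <- dataset$n_days
    class(out) <- c("activity_matrix", class(out))
    return(out)
  }

  # one spec row per (question, dimension); join on the stored answer key so
  # shared questions feed every dimension that references them
  spec_use <- qs[, c("id", "dimension", "weight", "answer_key")]
  joined <- dplyr::inner_join(daily, spec_use,
                              by = c("question_id" = "answer_key"),
                              relationship = "many-to-many")
  scored <- joined |>
    dplyr::group_by(.data$participant_id, .data$day_index, .data$dimension) |>
    dplyr::summarise(
      value = sum(.data$weight * ifelse(is.na(.data$a), 0, .data$a)),
      answered = sum(!is.na(.data$a)),
      .groups = "drop")

  exp_tab <- expected_slots(qs)
  scored$completeness <- scored$answered /
    exp_tab$administrations[match(scored$dimension, exp_tab$dimension)]
  scored$completeness <- pmin(scored$completeness, 1)
  scored$answered <- NULL
  scored <- scored[scored$completeness >= completeness_floor, ]

  out <- tibble::as_tibble(scored)
  attr(out, "n_days") <- dataset$n_days
  class(out) <- c("activity_matrix", class(out))
  out
}

#' Score one participant-day for one dimension
#'
#' @param record Daily-answer rows of a single participant-day (tibble with
#'   `question_id`, `a` or raw `answer`).
#' @param specs Daily-question specification tibble.
#' @param dimension One of the four coaching dimensions.
#' @return A one-row tibble: `participant_id`, `day_index`, `dimension`,
#'   `value`, `completeness`.
#' @export
daily_dimension_score <- function(record, specs, dimension) {
  if (!dimension %in% COACH_DIMENSIONS)
    abort_data(paste0("unknown coaching dimension '", dimension, "'"))
  stopifnot(length(unique(record$participant_id)) <= 1,
            length(unique(record$day_index)) <= 1)
  ds <- cohort_dataset(question_specs = specs,
                       variable_specs = default_variable_specs(),
                       daily = record,
                       n_days = max(record$day_index, 0L) + 1L)
  am <- build_activity_matrix(ds)
  row <- am[am$dimension == dimension, ]
  if (nrow(row) == 0) {
    row <- tibble::tibble(participant_id = record$participant_id[1],
                          day_index = record$day_index[1],
                          dimension = dimension, value = 0,
                          completeness = 0)
  }
  tibble::as_tibble(row)
}

#' Extract one participant's day-indexed activity series
#'
#' @param matrix An `activity_matrix`.
#' @param participant Participant id.
#' @param dimension Coaching dimension.
#' @param n_days Study window (defaults to the matrix attribute).
#' @return Numeric vector of length `n_days`; days without a score are `NA`.
#' @export
activity_series <- function(matrix, participant, dimension,
                            n_days = attr(matrix, "n_days")) {
  if (!participant %in% matrix$participant_id)
    abort_data(paste0("unknown participant '", participant, "'"))
  if (!dimension %in% COACH_DIMENSIONS)
    abort_data(paste0("unknown coaching dimension '", dimension, "'"))
  rows <- matrix[matrix$participant_id == participant &
                   matrix$dimension == dimension, ]
  out <- rep(NA_real_, n_days)
  out[rows$day_index + 1L] <- rows$value
  out
}

#' Export an activity matrix as long-format CSV
#'
#' @param matrix An `activity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(matrix, path) {
  readr::write_csv(tibble::as_tibble(matrix), path, progress = FALSE)
  invisible(path)
}
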