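# Cohort data model and CSV readers/writers.
#
# A cohort dataset holds two bodies of data: caregiver-supervised assessments
# at two timepoints (baseline / final) and daily self-reported questionnaire
# answers over the program window. Assessment values are stored post
# best-of-two reduction, keyed by variable id; daily answers are stored raw
# (label or count) together with their encoded index, keyed by answer_key so
# that a question shared between dimensions is stored once.

#' Encode a raw questionnaire answer as a nonnegative index
#'
#' Yes/No answers are coded 1/0. Ordered scales are coded by rank with the
#' smallest/least category at 0. Counts are nonnegative integers clipped at
#' the question's maximum.
#'
#' @param raw A single answer: a scale label (character) or a count (numeric).
#' @param spec One question-spec row (a one-row tibble or a list with fields
#'   `id`, `type`, `levels`, `max_count`).
#' @return Nonnegative integer answer index.
#' @examples
#' qs <- default_question_specs()
#' encode_answer("Yes", qs[qs$id == "cog_been_outside", ])   # 1
#' encode_answer("1-2 h", qs[qs$id == "light_activity", ])   # 2
#' encode_answer(7, qs[qs$id == "people_met", ])             # clipped to 4
#' @export
encode_answer <- function(raw, spec) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    spec <- list(id = spec$id, type = spec$type, levels = spec$levels[[1]],
                 max_count = spec$max_count)
  }
  if (length(raw) != 1 || is.na(raw))
    abort_data(paste0("missing or non-scalar answer for question '",
                      spec$id, "'"))
  if (spec$type %in% c("ordered", "binary")) {
    idx <- match(as.character(raw), spec$levels)
    if (is.na(idx))
      abort_data(paste0("unknown answer label '", raw, "' for question '",
                        spec$id, "'"))
    return(idx - 1L)
  }
  # count
  x <- suppressWarnings(as.numeric(raw))
  if (is.na(x) || x < 0 || x != floor(x))
    abort_data(paste0("answer for question '", spec$id,
                      "' must be a nonnegative integer count, got '",
                      raw, "'"))
  cap <- spec$max_count
  if (!is.na(cap)) x <- min(x, cap)
  as.integer(x)
}

# Vectorized encoding for one answer_key: `raw` character vector.
encode_answers_vec <- function(raw, spec_row) {
  type <- spec_row$type
  out <- rep(NA_integer_, length(raw))
  ok <- !is.na(raw)
  if (type %in% c("ordered", "binary")) {
    lev <- spec_row$levels[[1]]
    idx <- match(raw[ok], lev)
    if (anyNA(idx)) {
      bad <- unique(raw[ok][is.na(idx)])
      abort_data(paste0("unknown answer label(s) ",
                        paste0("'", bad, "'", collapse = ", "),
                        " for question '", spec_row$id, "'"))
    }
    out[ok] <- idx - 1L
  } else {
    x <- suppressWarnings(as.numeric(raw[ok]))
    if (any(is.na(x) | x < 0 | x != floor(x)))
      abort_data(paste0("non-count answer for question '", spec_row$id, "'"))
    cap <- spec_row$max_count
    if (!is.na(cap)) x <- pmin(x, cap)
    out[ok] <- as.integer(x)
  }
  out
}

# Map an encoded index back to the raw answer representation.
decode_answer_vec <- function(a, spec_row) {
  if (spec_row$type %in% c("ordered", "binary")) {
    spec_row$levels[[1]][a + 1L]
  } else {
    as.character(a)
  }
}

#' Reduce repeated assessment trials to the best result
#'
#' Variables measured in two trials keep the best of the two: the maximum
#' when a higher score is better (orientation +1), the minimum for timed
#' tests where lower is better (orientation -1).
#'
#' @param trials Numeric vector of 1 or 2 finite trial results.
#' @param spec One variable-spec row (needs fields `orientation`, `repeats`).
#' @return The selected trial value.
#' @export
best_of <- function(trials, spec) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  trials <- trials[!is.na(trials)]
  if (length(trials) == 0) abort_data("best_of: no trials supplied")
  if (length(trials) > spec$repeats)
    abort_data(paste0("best_of: more trials than spec allows (",
                      length(trials), " > ", spec$repeats, ")"))
  if (!all(is.finite(trials))) abort_data("best_of: non-finite trial value")
  if (spec$orientation > 0) max(trials) else min(trials)
}

#' Assemble and validate a cohort dataset
#'
#' @param question_specs Daily-question specification tibble.
#' @param variable_specs Assessment-variable specification tibble.
#' @param assessments Tibble: `participant_id`, `timepoint`
#'   (`"baseline"`/`"final"`), one numeric column per variable id
#'   (post best-of-two), `NA` = missing.
#' @param daily Tibble: `participant_id`, `day_index` (0-based), `slot`
#'   (0, or 0..2 for thrice-daily questions), `question_id` (the stored
#'   answer key), `answer` (raw), and optionally `a` (encoded index; computed
#'   when absent).
#' @param n_days Length of the study window in days (default 150).
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(question_specs = default_question_specs(),
                           variable_specs = default_variable_specs(),
                           assessments = NULL, daily = NULL,
                           n_days = 150L) {
  validate_question_specs(question_specs)
  validate_variable_specs(variable_specs)
  n_days <- as.integer(n_days)
  stopifnot(n_days >= 1)

  if (is.null(assessments)) {
    assessments <- tibble::tibble(participant_id = character(),
                                  timepoint = character())
  }
  if (is.null(daily)) {
    daily <- tibble::tibble(participant_id = character(),
                            day_index = integer(), slot = integer(),
                            question_id = character(), answer = character(),
                            a = integer())
  }
  assessments <- tibble::as_tibble(assessments)
  daily <- tibble::as_tibble(daily)

  if (!all(c("participant_id", "timepoint") %in% names(assessments)))
    abort_data("assessments need participant_id and timepoint columns")
  if (!all(assessments$timepoint %in% c("baseline", "final")))
    abort_data("timepoint must be 'baseline' or 'final'")
  if (anyDuplicated(assessments[, c("participant_id", "timepoint")]))
    abort_data("duplicate (participant_id, timepoint) in assessments")
  vals <- assessments[, setdiff(names(assessments),
                                c("participant_id", "timepoint")),
                      drop = FALSE]
  unknown_vars <- setdiff(names(vals), variable_specs$id)
  if (length(unknown_vars) > 0)
    abort_data(paste0("assessment column(s) not in variable specs: ",
                      paste(unknown_vars, collapse = ", ")))
  if (nrow(assessments) > 0) {
    num <- as.matrix(vals)
    if (any(!is.na(num) & !is.finite(num)))
      abort_data("non-finite assessment value")
    fin <- assessments$participant_id[assessments$timepoint == "final"]
    base <- assessments$participant_id[assessments$timepoint == "baseline"]
    orphans <- setdiff(fin, base)
    if (length(orphans) > 0)
      abort_data(paste0("final assessment without baseline for: ",
                        paste(orphans, collapse = ", ")))
  }

  need_daily <- c("participant_id", "day_index", "slot", "question_id",
                  "answer")
  miss <- setdiff(need_daily, names(daily))
  if (length(miss) > 0)
    abort_data(paste0("daily table missing column(s): ",
                      paste(miss, collapse = ", ")))
  if (nrow(daily) > 0) {
    if (any(daily$day_index < 0 | daily$day_index >= n_days))
      abort_data(paste0("day_index outside study window [0, ", n_days - 1,
                        "]"))
    keymap <- unique(question_specs[, c("answer_key", "type", "levels",
                                        "max_count", "administrations")])
    keymap <- keymap[!duplicated(keymap$answer_key), ]
    bad_keys <- setdiff(unique(daily$question_id), keymap$answer_key)
    if (length(bad_keys) > 0)
      abort_data(paste0("daily answers for unknown question(s): ",
                        paste(bad_keys, collapse = ", ")))
    adm <- keymap$administrations[match(daily$question_id,
                                        keymap$answer_key)]
    if (any(daily$slot < 0 | daily$slot >= adm))
      abort_data("administration slot outside the question's slots")
    if (!("a" %in% names(daily))) {
      daily$a <- NA_integer_
      for (key in unique(daily$question_id)) {
        i <- which(daily$question_id == key)
        kr <- keymap[keymap$answer_key == key, ]
        spec_like <- list(id = key, type = kr$type, levels = kr$levels,
                          max_count = kr$max_count)
        class(spec_like) <- "list"
        daily$a[i] <- encode_answers_vec(
          daily$answer[i],
          tibble::tibble(id = key, type = kr$type, levels = kr$levels,
                         max_count = kr$max_count))
      }
    }
  } else if (!("a" %in% names(daily))) {
    daily$a <- integer()
  }

  structure(
    list(question_specs = question_specs, variable_specs = variable_specs,
         assessments = assessments, daily = daily, n_days = n_days),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  np <- length(unique(x$assessments$participant_id))
  cat("<cohort_dataset> ", np, " participants, ",
      nrow(x$daily), " daily answers over ", x$n_days, " days, ",
      nrow(x$variable_specs), " assessment variables, ",
      nrow(x$question_specs), " question rows\n", sep = "")
  invisible(x)
}

participants <- function(dataset) {
  unique(dataset$assessments$participant_id[
    dataset$assessments$timepoint == "baseline"])
}

#' Read an assessment CSV
#'
#' Expected columns: `participant_id`, `timepoint` in `{baseline, final}`,
#' then one column per variable trial — `<id>` for single-trial variables,
#' `<id>_1`/`<id>_2` for two-trial variables. Repeated trials are reduced to
#' the best result according to the variable's orientation.
#'
#' @param path CSV file path.
#' @param variable_specs Assessment-variable specification tibble.
#' @return Tibble of assessment records (one column per variable id).
#' @export
read_assessment_csv <- function(path, variable_specs = default_variable_specs()) {
  validate_variable_specs(variable_specs)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("participant_id", "timepoint")) {
    if (!col %in% names(df))
      abort_data(paste0("assessment CSV missing required column '", col, "'"))
  }
  out <- tibble::tibble(participant_id = as.character(df$participant_id),
                        timepoint = df$timepoint)
  for (i in seq_len(nrow(variable_specs))) {
    vs <- variable_specs[i, ]
    if (vs$repeats == 1L) {
      if (!vs$id %in% names(df))
        abort_data(paste0("assessment CSV missing required column '",
                          vs$id, "'"))
      out[[vs$id]] <- as.numeric(df[[vs$id]])
    } else {
      cols <- paste0(vs$id, "_", seq_len(vs$repeats))
      missing_cols <- setdiff(cols, names(df))
      if (length(missing_cols) > 0)
        abort_data(paste0("assessment CSV missing required column '",
                          missing_cols[1], "'"))
      trials <- as.matrix(df[, cols])
      out[[vs$id]] <- apply(trials, 1, function(tr) {
        if (all(is.na(tr))) NA_real_ else best_of(tr, vs)
      })
    }
  }
  if (anyDuplicated(out[, c("participant_id", "timepoint")]))
    abort_data("duplicate (participant_id, timepoint) in assessment CSV")
  out
}

#' Read a daily-questionnaire CSV
#'
#' Expected columns: `participant_id`, `day_index`, `slot`, `question_id`,
#' `answer`. Answers are validated and encoded on ingestion.
#'
#' @param path CSV file path.
#' @param question_specs Daily-question specification tibble.
#' @param n_days Study window length used for the day-index bounds check.
#' @return Tibble of daily answers with encoded index column `a`.
#' @export
read_daily_csv <- function(path, question_specs = default_question_specs(),
                           n_days = 150L) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          day_index = readr::col_integer(),
                          slot = readr::col_integer(),
                          question_id = readr::col_character(),
                          answer = readr::col_character()))
  need <- c("participant_id", "day_index", "slot", "question_id", "answer")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort_data(paste0("daily CSV missing required column '", miss[1], "'"))
  ds <- cohort_dataset(question_specs = question_specs,
                       daily = df[, need], n_days = n_days)
  ds$daily
}

#' Write assessment records to CSV
#'
#' Values are written post best-of reduction in single `<id>` columns, which
#' [read_assessment_csv()] accepts for single-trial variables; two-trial
#' variables are written as identical `<id>_1`/`<id>_2` columns so the file
#' round-trips through the reader.
#'
#' @param assessments Assessment tibble (one column per variable id).
#' @param path Output path.
#' @param variable_specs Variable specification tibble.
#' @return `path`, invisibly.
#' @export
write_assessment_csv <- function(assessments, path,
                                 variable_specs = default_variable_specs()) {
  out <- assessments[, c("participant_id", "timepoint")]
  for (i in seq_len(nrow(variable_specs))) {
    vs <- variable_specs[i, ]
    if (!vs$id %in% names(assessments)) next
    if (vs$repeats == 1L) {
      out[[vs$id]] <- assessments[[vs$id]]
    } else {
      for (j in seq_len(vs$repeats))
        out[[paste0(vs$id, "_", j)]] <- assessments[[vs$id]]
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write daily answers to CSV
#'
#' @param daily Daily-answer tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  readr::write_csv(
    daily[, c("participant_id", "day_index", "slot", "question_id", "answer")],
    path, progress = FALSE)
  invisible(path)
}

#' Write a JSON summary of a dataset or result list
#'
#' @param x A `cohort_dataset` or any JSON-serializable result list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  if (inherits(x, "cohort_dataset")) {
    x <- list(
      n_participants = length(participants(x)),
      n_days = x$n_days,
      n_daily_answers = nrow(x$daily),
      variables = x$variable_specs$id,
      dimensions = unname(COACH_DIMENSIONS),
      timepoints = sort(unique(x$assessments$timepoint))
    )
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
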