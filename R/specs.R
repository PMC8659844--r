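# Question and assessment-variable specifications.
#
# A question spec row describes one daily-questionnaire item as it counts
# toward ONE coaching dimension. A handful of questions feed two dimensions
# (e.g. "Have you been outside your house?" counts for both Cognitive and
# Social): those appear as two rows sharing one `answer_key`, so a single
# stored answer feeds both dimensions with each row's own weight.

ACTIVITY_LEVELS_6 <- c(
  "None", "Less than 1 h", "1-2 h", "2-3 h", "3-4 h", "More than 4 h"
)
FOOD_GROUP_LEVELS <- c("None", "Less", "Equal", "More", "All")
YESNO_LEVELS <- c("No", "Yes")

q_row <- function(id, dimension, text, type, weight,
                  levels = NULL, max_count = NA_integer_,
                  administrations = 1L, answer_key = id) {
  tibble::tibble(
    id = id, dimension = dimension, text = text, type = type,
    levels = list(levels), max_count = as.integer(max_count),
    weight = weight, administrations = as.integer(administrations),
    answer_key = answer_key
  )
}

#' Default daily-questionnaire specification
#'
#' The built-in daily questionnaire: per-question answer scales, signed
#' importance weights within each coaching dimension, and administration
#' frequency (the three physical-activity questions and the five food-group
#' questions are asked three times a day; everything else once).
#'
#' Answer types are `"ordered"` (a fixed ascending label scale; the
#' least-active/smallest category encodes to 0), `"binary"` (No/Yes coded
#' 0/1) and `"count"` (a nonnegative integer clipped at `max_count`).
#' Questions shared between dimensions carry a common `answer_key`.
#'
#' @return A tibble with one row per (question, dimension) pair: columns
#'   `id`, `dimension`, `text`, `type`, `levels` (list column), `max_count`,
#'   `weight`, `administrations`, `answer_key`.
#' @export
default_question_specs <- function() {
  dplyr::bind_rows(
    # Physical: graded activity-duration scales, thrice daily
    q_row("light_activity", "Physical",
          "How much light physical activity have you performed?",
          "ordered", 1, levels = ACTIVITY_LEVELS_6, administrations = 3L),
    q_row("moderate_activity", "Physical",
          "How much moderate physical activity have you performed?",
          "ordered", 2, levels = ACTIVITY_LEVELS_6, administrations = 3L),
    q_row("vigorous_activity", "Physical",
          "How much vigorous physical activity have you performed?",
          "ordered", 3, levels = ACTIVITY_LEVELS_6, administrations = 3L),
    # Cognitive: six yes/no engagement items, each weight 1
    q_row("cog_been_outside", "Cognitive", "Have you been outside your house?",
          "binary", 1, levels = YESNO_LEVELS, answer_key = "been_outside"),
    q_row("cog_meals_outside", "Cognitive",
          "Have you eaten one or more meals outside of home?",
          "binary", 1, levels = YESNO_LEVELS, answer_key = "meals_outside"),
    q_row("cog_been_shop", "Cognitive", "Have you been to a shop?",
          "binary", 1, levels = YESNO_LEVELS, answer_key = "been_shop"),
    q_row("cog_prepared_food", "Cognitive",
          "Have you prepared your own food at least once?",
          "binary", 1, levels = YESNO_LEVELS, answer_key = "prepared_food"),
    q_row("artistic_pastime", "Cognitive",
          "Have you practiced an artistic pastime?",
          "binary", 1, levels = YESNO_LEVELS),
    q_row("read_anything", "Cognitive", "Have you read anything?",
          "binary", 1, levels = YESNO_LEVELS),
    # Social: contact counts capped at 4, shared outing items, a preference scale
    q_row("people_met", "Social", "How many people have you met?",
          "count", 3, max_count = 4L),
    q_row("people_phoned", "Social",
          "How many people have you talked on the phone with?",
          "count", 2, max_count = 4L),
    q_row("people_texted", "Social", "How many people have you texted?",
          "count", 1, max_count = 4L),
    q_row("soc_been_outside", "Social", "Have you been outside your house?",
          "binary", 2, levels = YESNO_LEVELS, answer_key = "been_outside"),
    q_row("soc_been_shop", "Social", "Have you been to a shop?",
          "binary", 2, levels = YESNO_LEVELS, answer_key = "been_shop"),
    q_row("social_preference", "Social",
          "Consider the social interactions you had, what would you prefer?",
          "ordered", 2,
          levels = c("Decrease a lot", "Decrease a little", "Not change",
                     "Increase a little", "Increase a lot")),
    # Nutritional: habits, capped counts (negative weights for sugar/salt/
    # alcohol), thrice-daily food-group scales, meal completeness
    q_row("nut_meals_outside", "Nutritional",
          "Have you eaten one or more meals outside of home?",
          "binary", 1, levels = YESNO_LEVELS, answer_key = "meals_outside"),
    q_row("nut_prepared_food", "Nutritional",
          "Have you prepared your own food at least once?",
          "binary", 1, levels = YESNO_LEVELS, answer_key = "prepared_food"),
    q_row("sugar_added", "Nutritional",
          "How many times have you added sugar to anything you have eaten?",
          "count", -1, max_count = 4L),
    q_row("salt_added", "Nutritional",
          "How many times have you added salt to anything you have eaten or drunk?",
          "count", -2, max_count = 4L),
    q_row("water_glasses", "Nutritional",
          "How much water did you have? (unit: water glasses)",
          "count", 2, max_count = 10L),
    q_row("alcohol_units", "Nutritional",
          "How many units of alcohol did you have?",
          "count", -2, max_count = 10L),
    q_row("times_eaten", "Nutritional",
          "How many times did you eat something during the day?",
          "count", 1, max_count = 4L),
    q_row("satiety", "Nutritional",
          "How satisfied were you when you stopped eating?",
          "ordered", 3,
          levels = c("I ate too little", "I was just satisfied",
                     "I ate slightly too much", "I ate too much")),
    q_row("fg_vegetables_fruits", "Nutritional",
          "Food groups: Vegetables and Fruits",
          "ordered", 2, levels = FOOD_GROUP_LEVELS, administrations = 3L),
    q_row("fg_dairy", "Nutritional", "Food groups: Dairy Products",
          "ordered", 1, levels = FOOD_GROUP_LEVELS, administrations = 3L),
    q_row("fg_bread_cereals_potatoes", "Nutritional",
          "Food groups: Bread, Cereals and Potatoes",
          "ordered", 1, levels = FOOD_GROUP_LEVELS, administrations = 3L),
    q_row("fg_oils", "Nutritional", "Food groups: Oils",
          "ordered", 1, levels = FOOD_GROUP_LEVELS, administrations = 3L),
    q_row("fg_meat_fish_eggs", "Nutritional",
          "Food groups: Meat, Fish and Eggs",
          "ordered", 2, levels = FOOD_GROUP_LEVELS, administrations = 3L),
    q_row("what_eaten", "Nutritional", "What have you eaten?",
          "ordered", 3, levels = c("Nothing", "Light meal", "Complete meal"))
  )
}

v_row <- function(id, dimension, orientation, repeats = 1L) {
  tibble::tibble(id = id, dimension = dimension,
                 orientation = orientation, repeats = as.integer(repeats))
}

#' Default assessment-variable specification
#'
#' The built-in baseline/final assessment battery: Fullerton Functional
#' Fitness items (Physical), MoCA, MCS-A and MAI (Cognitive), and the MNA
#' mini (Nutritional). `orientation` is +1 when a higher score is better
#' and -1 when lower is better (the timed Foot Up and Go test). Variables
#' with `repeats = 2` are measured in two trials and reduced to the best
#' result on ingestion.
#'
#' @return A tibble with columns `id`, `dimension`, `orientation`, `repeats`.
#' @export
default_variable_specs <- function() {
  dplyr::bind_rows(
    v_row("chair_stand", "Physical", 1),
    v_row("arm_curl", "Physical", 1),
    v_row("two_minute_step", "Physical", 1),
    v_row("chair_sit_reach", "Physical", 1, repeats = 2L),
    v_row("back_scratch", "Physical", 1, repeats = 2L),
    v_row("foot_up_go", "Physical", -1, repeats = 2L),  # timed: lower is better
    v_row("moca", "Cognitive", 1),
    v_row("mcs_a", "Cognitive", 1),
    v_row("mai", "Cognitive", 1),
    v_row("mna_mini", "Nutritional", 1)
  )
}

validate_question_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  needed <- c("id", "dimension", "type", "levels", "max_count", "weight",
              "administrations", "answer_key")
  miss <- setdiff(needed, names(specs))
  if (length(miss) > 0)
    abort_data(paste0("question specs missing column(s): ",
                      paste(miss, collapse = ", ")))
  if (anyDuplicated(specs$id))
    abort_data("duplicate question spec ids")
  if (!all(specs$dimension %in% COACH_DIMENSIONS))
    abort_data("question spec with unknown coaching dimension")
  if (!all(specs$administrations %in% c(1L, 3L)))
    abort_data("administrations must be 1 or 3")
  ord <- specs$type %in% c("ordered", "binary")
  n_lev <- vapply(specs$levels, length, integer(1))
  if (any(ord & n_lev < 2))
    abort_data("ordered scales need at least 2 labels")
  # a shared answer_key must carry one answer type and scale
  for (key in unique(specs$answer_key)) {
    rows <- specs[specs$answer_key == key, ]
    if (length(unique(rows$type)) > 1)
      abort_data(paste0("answer_key '", key, "' mixes answer types"))
  }
  invisible(specs)
}

validate_variable_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  needed <- c("id", "dimension", "orientation", "repeats")
  miss <- setdiff(needed, names(specs))
  if (length(miss) > 0)
    abort_data(paste0("variable specs missing column(s): ",
                      paste(miss, collapse = ", ")))
  if (anyDuplicated(specs$id)) abort_data("duplicate variable spec ids")
  if (!all(specs$orientation %in% c(-1, 1)))
    abort_data("orientation must be +1 or -1")
  if (!all(specs$repeats %in% c(1L, 2L)))
    abort_data("repeats must be 1 or 2")
  if (!all(specs$dimension %in% COACH_DIMENSIONS))
    abort_data("variable spec with unknown coaching dimension")
  invisible(specs)
}

#' Write question/variable specifications to YAML
#'
#' @param question_specs Tibble from [default_question_specs()] or compatible.
#' @param variable_specs Tibble from [default_variable_specs()] or compatible.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_specs_yaml <- function(question_specs, variable_specs, path) {
  qs <- lapply(seq_len(nrow(question_specs)), function(i) {
    r <- question_specs[i, ]
    list(id = r$id, dimension = r$dimension, text = r$text, type = r$type,
         levels = r$levels[[1]],
         max_count = if (is.na(r$max_count)) NULL else r$max_count,
         weight = r$weight, administrations = r$administrations,
         answer_key = r$answer_key)
  })
  vs <- lapply(seq_len(nrow(variable_specs)), function(i) {
    r <- variable_specs[i, ]
    list(id = r$id, dimension = r$dimension, orientation = r$orientation,
         repeats = r$repeats)
  })
  yaml::write_yaml(list(questions = qs, variables = vs), path)
  invisible(path)
}

#' Read question/variable specifications from YAML
#'
#' @param path YAML file written by [write_specs_yaml()] (or hand-edited in
#'   the same shape).
#' @return List with elements `question_specs` and `variable_specs`.
#' @export
read_specs_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  qs <- dplyr::bind_rows(lapply(raw$questions, function(q) {
    q_row(q$id, q$dimension, q$text %||% q$id, q$type, q$weight,
          levels = unlist(q$levels),
          max_count = q$max_count %||% NA_integer_,
          administrations = q$administrations %||% 1L,
          answer_key = q$answer_key %||% q$id)
  }))
  vs <- dplyr::bind_rows(lapply(raw$variables, function(v) {
    v_row(v$id, v$dimension, v$orientation, v$repeats %||% 1L)
  }))
  validate_question_specs(qs)
  validate_variable_specs(vs)
  list(question_specs = qs, variable_specs = vs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
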