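# System Usability Scale (SUS) scoring and questionnaire summaries.
#
# SUS: ten items answered on a 1-5 agreement scale; odd items are
# positively phrased, even items negatively. A subject's score is
#
#   2.5 * [ sum_odd (a - 1) + sum_even (5 - a) ]   in [0, 100].
#
# Because this is linear in the answers, the cohort mean SUS is computable
# from per-question answer multisets even when the subject pairing is
# unknown (answers published sorted per question): the mean is invariant
# to any pairing consistent with the multisets.

#' SUS score of one subject
#'
#' @param answers Numeric vector of 10 answers in 1..5 (items in standard
#'   SUS order; odd items positively phrased).
#' @return Score in [0, 100].
#' @examples
#' sus_score(rep(3, 10))  # 50, the neutral midpoint
#' @export
sus_score <- function(answers) {
  if (length(answers) != 10)
    abort_data("SUS needs exactly 10 answers")
  if (any(is.na(answers)) || any(answers < 1 | answers > 5) ||
      any(answers != floor(answers)))
    abort_data("SUS answers must be integers in 1..5")
  odd <- answers[seq(1, 9, 2)]
  even <- answers[seq(2, 10, 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Mean SUS score from per-question answer multisets
#'
#' Computes the cohort mean SUS from the multiset of answers to each of the
#' 10 items, without knowing which answers belong to the same subject.
#' Exact: the mean SUS is `2.5 * [sum_odd (mean_q - 1) + sum_even (5 -
#' mean_q)]`, invariant to the pairing.
#'
#' @param multisets List of 10 numeric vectors (item 1..10), all the same
#'   length, answers in 1..5; or a 10-row matrix/data frame.
#' @return Mean SUS score in [0, 100].
#' @export
sus_mean_from_multisets <- function(multisets) {
  if (is.matrix(multisets) || is.data.frame(multisets)) {
    multisets <- lapply(seq_len(nrow(multisets)), function(i)
      as.numeric(multisets[i, ]))
  }
  if (length(multisets) != 10)
    abort_data("need answer multisets for exactly 10 items")
  sizes <- vapply(multisets, length, integer(1))
  if (length(unique(sizes)) != 1 || sizes[1] == 0)
    abort_data("all 10 answer multisets must have the same nonzero size")
  for (m in multisets)
    if (any(is.na(m)) || any(m < 1 | m > 5))
      abort_data("SUS answers must be in 1..5")
  means <- vapply(multisets, mean, numeric(1))
  odd <- means[seq(1, 9, 2)]
  even <- means[seq(2, 10, 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Mean and sample standard deviation of a response vector
#'
#' @param values Non-empty numeric vector.
#' @return List with `mean`, `sd` (`NA` with `sd_defined = FALSE` for a
#'   single value) and `n`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort_data("summary_stats needs values")
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       sd_defined = length(values) > 1,
       n = length(values))
}

#' Read a SUS/questionnaire answer CSV
#'
#' Two layouts are auto-detected from the header: per-subject rows
#' (`subject_id, q1..q10`) or per-question answer multisets in long form
#' (`item, answer`; pairing unknown).
#'
#' @param path CSV file path.
#' @return For the per-subject layout, a numeric matrix subjects x 10; for
#'   the per-question layout, a list of answer multisets keyed by item.
#' @export
read_sus_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("subject_id" %in% names(df)) {
    qcols <- paste0("q", 1:10)
    miss <- setdiff(qcols, names(df))
    if (length(miss) > 0)
      abort_data(paste0("per-subject SUS CSV missing column '", miss[1], "'"))
    m <- as.matrix(df[, qcols])
    rownames(m) <- df$subject_id
    return(m)
  }
  if (all(c("item", "answer") %in% names(df))) {
    items <- unique(df$item)
    items <- if (all(grepl("^q[0-9]+$", items))) {
      items[order(as.integer(sub("^q", "", items)))]
    } else sort(items)
    return(lapply(stats::setNames(items, items), function(i)
      as.numeric(df$answer[df$item == i])))
  }
  abort_data("unrecognized SUS CSV layout (need subject_id,q1..q10 or item,answer)")
}

#' Bundled nine-subject SUS responses
#'
#' The per-question answer multisets collected in a nine-subject usability
#' evaluation of the interactive coaching-analytics interface this package
#' re-implements headlessly (answers are published sorted within item, so
#' the subject pairing is unknown).
#'
#' @return List of 10 answer multisets (items `q1`..`q10`, 9 answers each).
#' @export
sus_example_responses <- function() {
  path <- system.file("extdata", "sus_responses.csv",
                      package = "cohortcoach", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  items <- paste0("q", 1:10)
  lapply(stats::setNames(items, items), function(i)
    as.numeric(df$answer[df$item == i]))
}
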