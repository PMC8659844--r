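# Synthetic cohort generator with exported ground truth.
#
# Emulates the structure the pipeline assumes: ~68 participants followed
# for ~150 days, two assessments (baseline/final), four coaching
# dimensions. Participants belong to planted groups that differ in
# baseline assessment level (shifts in standardized units) and in daily
# activity level; day-to-day activity fluctuates with AR(1) noise and is
# inverted into valid questionnaire answers, so the encoded weighted-sum
# scores follow the planted activity process. Optional effects link a
# participant's mean activity in one dimension to their final-baseline
# change in another, group-conditionally. Everything is deterministic
# under a fixed seed and ships with the planted truth.

# Raw-scale location/spread per assessment variable used to map
# standardized shifts onto realistic instrument scales (cohort-level
# magnitudes typical for Fullerton battery, MoCA, MCS-A, MAI, MNA mini).
SYNTH_VARIABLE_MOMENTS <- tibble::tribble(
  ~id,               ~mean,  ~sd,
  "chair_stand",      12.5,   4.6,
  "arm_curl",         16.54,  5.1,
  "two_minute_step",  66.01, 25.6,
  "chair_sit_reach",  -3.58, 12.5,
  "back_scratch",     -9.34, 13.8,
  "foot_up_go",        6.11,  1.6,
  "moca",             25.46,  3.0,
  "mcs_a",             3.22,  2.3,
  "mai",               6.16,  1.1,
  "mna_mini",          4.23,  1.3
)

#' Synthetic cohort configuration
#'
#' @param n_participants Cohort size including outliers (default 68).
#' @param n_days Study window length (default 150).
#' @param seed Integer seed; the generator is byte-deterministic under it.
#' @param groups List of planted groups, each a list with `proportion`
#'   (of the non-outlier cohort), `shift` (named numeric, baseline mean
#'   shift per variable in standardized units; unnamed variables shift 0)
#'   and `activity` (named numeric, mean daily activity level per
#'   dimension in weighted-score units).
#' @param effects List of planted links, each a list with `group` (index
#'   into `groups`), `from` (activity dimension), `to` (assessment
#'   dimension) and `beta`: the change in `to` (standardized units) per
#'   within-group standard deviation of mean `from` activity.
#' @param ar_rho AR(1) coefficient of day-to-day activity noise (default 0.6).
#' @param ar_sd Innovation standard deviation of the AR(1) process
#'   (weighted-score units, default 2).
#' @param baseline_sd Within-group spread of baseline z-scores (default 1).
#' @param personal_activity_sd Between-participant spread of mean activity
#'   within a group (default 1.5).
#' @param change_noise_sd Noise on the standardized final-baseline change
#'   (default 0.3).
#' @param missing_rate Probability that any single daily answer goes
#'   unrecorded (default 0.05).
#' @param n_outliers Participants drawn far from every group (default 4).
#' @param outlier_shift Magnitude of the outliers' baseline shift in
#'   standardized units (default 6).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 68L, n_days = 150L, seed = 1L,
                             groups = NULL, effects = NULL,
                             ar_rho = 0.6, ar_sd = 2, baseline_sd = 1,
                             personal_activity_sd = 1.5,
                             change_noise_sd = 0.3, missing_rate = 0.05,
                             n_outliers = 4L, outlier_shift = 6) {
  if (is.null(groups)) {
    groups <- list(
      list(proportion = 0.6,
           shift = c(mna_mini = -1.5, moca = -0.3),
           activity = c(Physical = 10, Cognitive = 3, Social = 8,
                        Nutritional = 12)),
      list(proportion = 0.4,
           shift = c(mna_mini = 1.0),
           activity = c(Physical = 10, Cognitive = 3, Social = 8,
                        Nutritional = 20))
    )
  }
  if (is.null(effects)) {
    effects <- list(list(group = 1L, from = "Nutritional", to = "Physical",
                         beta = 0.5))
  }
  props <- vapply(groups, function(g) g$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-8)
    abort_data("group proportions must sum to 1")
  if (ar_rho < 0 || ar_rho >= 1) abort_data("ar_rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate > 1)
    abort_data("missing_rate must be in [0, 1]")
  structure(
    list(n_participants = as.integer(n_participants),
         n_days = as.integer(n_days), seed = as.integer(seed),
         groups = groups, effects = effects, ar_rho = ar_rho, ar_sd = ar_sd,
         baseline_sd = baseline_sd,
         personal_activity_sd = personal_activity_sd,
         change_noise_sd = change_noise_sd, missing_rate = missing_rate,
         n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift),
    class = "synthetic_config")
}

# slot-level allocation table of a dimension: one row per (answer_key, slot)
dimension_slots <- function(question_specs, dim) {
  rows <- question_specs[question_specs$dimension == dim, ]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    cap <- if (r$type %in% c("ordered", "binary"))
      length(r$levels[[1]]) - 1L else r$max_count
    for (s in seq_len(r$administrations) - 1L) {
      out[[length(out) + 1]] <- tibble::tibble(
        answer_key = r$answer_key, slot = s, weight = r$weight,
        cap = as.integer(cap))
    }
  }
  dplyr::bind_rows(out)
}

# representable daily score range of a dimension
dimension_score_range <- function(question_specs, dim) {
  sl <- dimension_slots(question_specs, dim)
  c(lo = sum(pmin(sl$weight, 0) * sl$cap),
    hi = sum(pmax(sl$weight, 0) * sl$cap))
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `dataset`
#'   (a `cohort_dataset`), `truth` (planted group labels, outlier flags,
#'   effect coefficients, per-participant mean planted activity) and
#'   `trials` (the raw two-trial assessment table underlying the
#'   best-of-two reduced values).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  qs <- default_question_specs()
  vs <- default_variable_specs()
  n <- config$n_participants
  n_days <- config$n_days
  n_out <- min(config$n_outliers, n)
  n_main <- n - n_out
  G <- length(config$groups)

  # ---- group assignment -------------------------------------------------
  props <- vapply(config$groups, function(g) g$proportion, numeric(1))
  counts <- floor(props * n_main)
  counts[1] <- counts[1] + (n_main - sum(counts))
  group <- c(rep(seq_len(G), counts), rep(NA_integer_, n_out))
  ids <- sprintf("P%03d", seq_len(n))
  is_outlier <- is.na(group)

  # ---- baseline assessments --------------------------------------------
  vars <- vs$id
  mom <- SYNTH_VARIABLE_MOMENTS[match(vars, SYNTH_VARIABLE_MOMENTS$id), ]
  zb <- matrix(rnorm(n * length(vars), sd = config$baseline_sd),
               n, length(vars), dimnames = list(ids, vars))
  for (g in seq_len(G)) {
    shift <- config$groups[[g]]$shift
    for (v in names(shift))
      zb[which(group == g), v] <- zb[which(group == g), v] + shift[[v]]
  }
  for (i in which(is_outlier)) {
    signs <- sample(c(-1, 1), length(vars), replace = TRUE)
    zb[i, ] <- zb[i, ] + signs * config$outlier_shift
  }
  raw_b <- sweep(sweep(zb, 2, mom$sd, "*"), 2, mom$mean, "+")

  # ---- daily activity targets ------------------------------------------
  act_mean <- sapply(COACH_DIMENSIONS, function(d)
    mean(vapply(config$groups, function(g) g$activity[[d]], numeric(1))))
  level <- matrix(NA_real_, n, 4, dimnames = list(ids, COACH_DIMENSIONS))
  for (d in COACH_DIMENSIONS) {
    rng <- dimension_score_range(qs, d)
    for (g in seq_len(G)) {
      lv <- config$groups[[g]]$activity[[d]]
      if (is.null(lv) || lv < rng["lo"] || lv > rng["hi"])
        abort_data(paste0("infeasible activity target for dimension '", d,
                          "' in group ", g))
      level[which(group == g), d] <- lv
    }
    level[is_outlier, d] <- act_mean[[d]]
    level[, d] <- level[, d] +
      rnorm(n, sd = config$personal_activity_sd)
  }

  # stationary AR(1) noise around the personal level, clamped to the
  # representable score range of each dimension
  target <- array(NA_real_, c(n, n_days, 4),
                  dimnames = list(ids, NULL, COACH_DIMENSIONS))
  stat_sd <- config$ar_sd / sqrt(1 - config$ar_rho^2)
  for (d in seq_along(COACH_DIMENSIONS)) {
    e <- matrix(0, n, n_days)
    e[, 1] <- rnorm(n, sd = stat_sd)
    for (t in 2:n_days)
      e[, t] <- config$ar_rho * e[, t - 1] + rnorm(n, sd = config$ar_sd)
    rng <- dimension_score_range(qs, COACH_DIMENSIONS[d])
    target[, , d] <- pmin(pmax(level[, COACH_DIMENSIONS[d]] + e,
                               rng["lo"]), rng["hi"])
  }

  # ---- invert targets into valid answers -------------------------------
  # cells are (participant, day) pairs; answers live per (key, slot)
  n_cells <- n * n_days
  cell_p <- rep(ids, times = n_days)
  cell_day <- rep(seq_len(n_days) - 1L, each = n)
  ans <- list()  # "<key>#<slot>" -> integer vector over cells

  for (d in COACH_DIMENSIONS) {
    sl <- dimension_slots(qs, d)
    keyslot <- paste0(sl$answer_key, "#", sl$slot)
    fixed <- rep(0, n_cells)
    free <- logical(nrow(sl))
    for (i in seq_len(nrow(sl))) {
      if (!is.null(ans[[keyslot[i]]])) {
        fixed <- fixed + sl$weight[i] * ans[[keyslot[i]]]
      } else {
        free[i] <- TRUE
      }
    }
    r <- round(as.vector(target[, , d])) - fixed
    # greedy allocation: strongest positive weights first, then (for
    # negative residuals) strongest negative weights
    ord <- c(which(free & sl$weight > 0)[order(-sl$weight[free & sl$weight > 0])],
             which(free & sl$weight < 0)[order(sl$weight[free & sl$weight < 0])])
    for (i in ord) {
      w <- sl$weight[i]; cap <- sl$cap[i]
      if (w > 0) {
        a <- ifelse(r > 0, pmin(cap, r %/% w), 0L)
      } else {
        a <- ifelse(r < 0, pmin(cap, r %/% w), 0L)
      }
      a <- as.integer(a)
      r <- r - w * a
      ans[[keyslot[i]]] <- a
    }
  }

  # ---- effects: final assessments --------------------------------------
  mean_act <- apply(target, c(1, 3), mean)
  change <- matrix(rnorm(n * 4, sd = config$change_noise_sd), n, 4,
                   dimnames = list(ids, COACH_DIMENSIONS))
  for (ef in config$effects) {
    members <- which(group == ef$group)
    if (length(members) < 2) next
    x <- mean_act[members, ef$from]
    zact <- (x - mean(x)) / stats::sd(x)
    change[members, ef$to] <- change[members, ef$to] + ef$beta * zact
  }
  zf <- zb
  for (i in seq_len(nrow(vs))) {
    v <- vs$id[i]
    zf[, v] <- zb[, v] + vs$orientation[i] * change[, vs$dimension[i]] +
      rnorm(n, sd = 0.1)
  }
  raw_f <- sweep(sweep(zf, 2, mom$sd, "*"), 2, mom$mean, "+")

  # ---- two-trial table: the kept value is the best of the two ----------
  trials <- list()
  for (tp in c("baseline", "final")) {
    raw <- if (tp == "baseline") raw_b else raw_f
    for (i in which(vs$repeats == 2L)) {
      v <- vs$id[i]
      worse <- raw[, v] - vs$orientation[i] * abs(rnorm(n, sd = 0.2)) *
        mom$sd[i]
      first_is_best <- runif(n) < 0.5
      trials[[length(trials) + 1]] <- tibble::tibble(
        participant_id = ids, timepoint = tp, variable = v,
        trial_1 = ifelse(first_is_best, raw[, v], worse),
        trial_2 = ifelse(first_is_best, worse, raw[, v]))
    }
  }
  trials <- dplyr::bind_rows(trials)

  assessments <- dplyr::bind_rows(
    tibble::as_tibble(cbind(
      tibble::tibble(participant_id = ids, timepoint = "baseline"),
      tibble::as_tibble(raw_b))),
    tibble::as_tibble(cbind(
      tibble::tibble(participant_id = ids, timepoint = "final"),
      tibble::as_tibble(raw_f))))

  # ---- emit daily table with missingness -------------------------------
  keymap <- qs[!duplicated(qs$answer_key), ]
  daily_parts <- lapply(names(ans), function(ks) {
    parts <- strsplit(ks, "#", fixed = TRUE)[[1]]
    key <- parts[1]; slot <- as.integer(parts[2])
    a <- ans[[ks]]
    keep <- runif(n_cells) >= config$missing_rate
    kr <- keymap[keymap$answer_key == key, ]
    tibble::tibble(participant_id = cell_p[keep],
                   day_index = cell_day[keep], slot = slot,
                   question_id = key,
                   answer = decode_answer_vec(a[keep], kr),
                   a = a[keep])
  })
  daily <- dplyr::bind_rows(daily_parts)
  daily <- daily[order(daily$participant_id, daily$day_index,
                       daily$question_id, daily$slot), ]

  dataset <- cohort_dataset(question_specs = qs, variable_specs = vs,
                            assessments = assessments, daily = daily,
                            n_days = n_days)
  truth <- list(
    groups = tibble::tibble(participant_id = ids,
                            group = ifelse(is_outlier, NA_integer_, group),
                            outlier = is_outlier),
    effects = config$effects,
    mean_activity = tibble::as_tibble(cbind(
      tibble::tibble(participant_id = ids),
      tibble::as_tibble(mean_act)))
  )
  structure(list(dataset = dataset, truth = truth, trials = trials,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV + JSON files
#'
#' Emits `assessments.csv` (with the two-trial columns for twice-measured
#' variables), `daily.csv` and `truth.json` into a directory, in the exact
#' schemas the readers ingest.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- cohort$dataset
  vs <- ds$variable_specs
  out <- ds$assessments[, c("participant_id", "timepoint")]
  for (i in seq_len(nrow(vs))) {
    v <- vs$id[i]
    if (vs$repeats[i] == 1L) {
      out[[v]] <- ds$assessments[[v]]
    } else {
      tr <- cohort$trials[cohort$trials$variable == v, ]
      key <- paste(ds$assessments$participant_id, ds$assessments$timepoint)
      tkey <- paste(tr$participant_id, tr$timepoint)
      out[[paste0(v, "_1")]] <- tr$trial_1[match(key, tkey)]
      out[[paste0(v, "_2")]] <- tr$trial_2[match(key, tkey)]
    }
  }
  readr::write_csv(out, file.path(dir, "assessments.csv"), progress = FALSE)
  write_daily_csv(ds$daily, file.path(dir, "daily.csv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(groups = truth$groups, effects = truth$effects,
         mean_activity = truth$mean_activity),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
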