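qs <- default_question_specs()
vs <- default_variable_specs()
spec_of <- function(id) qs[qs$id == id, ]
vspec_of <- function(id) vs[vs$id == id, ]

test_that("answers encode to rank indices with the smallest category at 0", {
  expect_identical(encode_answer("Yes", spec_of("cog_been_outside")), 1L)
  expect_identical(encode_answer("No", spec_of("cog_been_outside")), 0L)
  expect_identical(encode_answer("None", spec_of("light_activity")), 0L)
  expect_identical(encode_answer("1-2 h", spec_of("light_activity")), 2L)
  expect_identical(encode_answer("More than 4 h", spec_of("light_activity")),
                   5L)
  # bounded counts clip at the stated maximum
  expect_identical(encode_answer(7, spec_of("people_met")), 4L)
  expect_identical(encode_answer(2, spec_of("people_met")), 2L)
  # preference scale coded ascending from "Decrease a lot" = 0
  expect_identical(encode_answer("Decrease a lot", spec_of("social_preference")),
                   0L)
  expect_identical(encode_answer("Increase a lot", spec_of("social_preference")),
                   4L)
})

test_that("encoding rejects unknown labels and negative counts by name", {
  expect_error(encode_answer("Maybe", spec_of("cog_been_outside")),
               "Maybe.*cog_been_outside|cog_been_outside.*Maybe")
  expect_error(encode_answer(-1, spec_of("people_met")), "nonnegative")
})

test_that("encoding is monotone in the ordered-scale rank", {
  for (id in c("light_activity", "social_preference", "satiety",
               "fg_vegetables_fruits", "what_eaten")) {
    sp <- spec_of(id)
    codes <- vapply(sp$levels[[1]], encode_answer, integer(1), spec = sp)
    expect_identical(unname(codes), seq_along(sp$levels[[1]]) - 1L)
  }
})

test_that("best_of selects the orientation-corrected extremum", {
  expect_equal(best_of(c(-5.29, -3.58), vspec_of("chair_sit_reach")), -3.58)
  expect_equal(best_of(c(6.55, 6.11), vspec_of("foot_up_go")), 6.11)
  expect_equal(best_of(12.5, vspec_of("chair_stand")), 12.5)
  expect_error(best_of(numeric(0), vspec_of("chair_stand")), "no trials")
  # property: equals direct extremum for random pairs
  set.seed(1)
  for (i in 1:50) {
    tr <- rnorm(2)
    expect_equal(best_of(tr, vspec_of("back_scratch")), max(tr))
    expect_equal(best_of(tr, vspec_of("foot_up_go")), min(tr))
  }
})

test_that("cohort CSVs round-trip through write and read", {
  co <- tiny_cohort(n = 3, n_days = 10)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)

  a2 <- read_assessment_csv(file.path(dir, "assessments.csv"))
  ds_a <- co$dataset$assessments
  expect_equal(as.data.frame(a2[order(a2$participant_id, a2$timepoint), ]),
               as.data.frame(ds_a[order(ds_a$participant_id, ds_a$timepoint), ]),
               tolerance = 1e-12)

  d2 <- read_daily_csv(file.path(dir, "daily.csv"), n_days = 10)
  d1 <- co$dataset$daily
  key <- function(d) paste(d$participant_id, d$day_index, d$question_id,
                           d$slot)
  d2 <- d2[order(key(d2)), ]
  d1 <- d1[order(key(d1)), ]
  expect_equal(d2$answer, d1$answer)
  expect_equal(d2$a, d1$a)
})

assessment_header <- function() {
  vs <- default_variable_specs()
  cols <- unlist(lapply(seq_len(nrow(vs)), function(i) {
    if (vs$repeats[i] == 1L) vs$id[i]
    else paste0(vs$id[i], "_", seq_len(vs$repeats[i]))
  }))
  paste(c("participant_id", "timepoint", cols), collapse = ",")
}
writeLines_file <- function(dir, name, lines) {
  p <- file.path(dir, name)
  writeLines(lines, p)
  p
}

test_that("readers validate schema, window bounds and duplicates", {
  dir <- withr::local_tempdir()
  # valid header, empty data section -> zero participants
  hdr <- read_assessment_csv(
    writeLines_file(dir, "empty.csv", assessment_header()))
  expect_identical(nrow(hdr), 0L)

  # missing required column is named in the error
  writeLines(c("participant_id,chair_stand", "P1,12"),
             file.path(dir, "bad.csv"))
  expect_error(read_assessment_csv(file.path(dir, "bad.csv")), "timepoint")

  # duplicate (participant, timepoint)
  co <- tiny_cohort(n = 2, n_days = 5)
  dup <- co$dataset$assessments[c(1, 1, 2), ]
  expect_error(cohort_dataset(assessments = dup), "duplicate")

  # final without baseline
  orphan <- co$dataset$assessments[co$dataset$assessments$timepoint == "final", ][1, ]
  expect_error(cohort_dataset(assessments = orphan), "without baseline")

  # day_index out of window
  d <- co$dataset$daily
  d$day_index[1] <- 5L
  expect_error(cohort_dataset(assessments = co$dataset$assessments,
                              daily = d, n_days = 5),
               "outside study window")
})

test_that("specification YAML round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "specs.yaml")
  write_specs_yaml(qs, vs, p)
  back <- read_specs_yaml(p)
  expect_equal(back$question_specs$id, qs$id)
  expect_equal(back$question_specs$weight, qs$weight)
  expect_equal(back$question_specs$answer_key, qs$answer_key)
  expect_equal(back$variable_specs, vs, ignore_attr = TRUE)
})

test_that("default question weights use the documented signed vocabulary", {
  expect_true(all(qs$weight %in% c(-2, -1, 1, 2, 3)))
  expect_true(all(qs$administrations %in% c(1L, 3L)))
})
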