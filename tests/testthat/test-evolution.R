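# a hand-built standardization model for improvement tests
toy_model <- function(vars, means, sds) {
  m <- tibble::tibble(variable = vars, mean = means, sd = sds,
                      lower = -Inf, upper = Inf,
                      n_used = 10L, degenerate = FALSE)
  class(m) <- c("standardization_model", class(m))
  m
}

test_that("improvement is the orientation-corrected mean standardized change", {
  vs <- default_variable_specs()
  model <- toy_model(vs$id, rep(0, nrow(vs)), rep(1, nrow(vs)))
  base <- tibble::as_tibble(as.list(setNames(rep(1, nrow(vs)), vs$id)))

  # final = baseline -> 0
  expect_equal(improvement(base, base, model, vs, "Cognitive"), 0)

  # one-variable dimension (Nutritional = mna_mini), z rises by 0.7
  fin <- base; fin$mna_mini <- base$mna_mini + 0.7
  expect_equal(improvement(base, fin, model, vs, "Nutritional"), 0.7)

  # orientation -1: foot_up_go time drops by 0.4 -> positive improvement
  model1 <- toy_model("foot_up_go", 6, 1)
  vs1 <- vs[vs$id == "foot_up_go", ]
  b <- tibble::tibble(foot_up_go = 6.4); f <- tibble::tibble(foot_up_go = 6.0)
  expect_equal(improvement(b, f, model1, vs1, "Physical"), 0.4)

  # mean over the dimension's variables
  fin2 <- base
  fin2$moca <- base$moca + 0.3
  fin2$mai <- base$mai - 0.6
  expect_equal(improvement(base, fin2, model, vs, "Cognitive"),
               (0.3 + 0 - 0.6) / 3)

  expect_error(improvement(base, fin, model, vs, "Social"), "no usable")
})

test_that("categorize maps change to color category and shade", {
  expect_equal(categorize(0, eps = 0.1)$category, "same")
  expect_equal(categorize(0, eps = 0.1)$shade, 0)
  out <- categorize(c(-0.2, 0.4), eps = 0.1, max_abs = 0.4)
  expect_equal(out$category, c("worsened", "improved"))
  expect_equal(out$shade, c(0.5, 1))

  # odd about the yellow band: negating change swaps the category at
  # identical shade
  set.seed(41)
  ch <- runif(50, -2, 2)
  pos <- categorize(ch, eps = 0.15, max_abs = 2)
  neg <- categorize(-ch, eps = 0.15, max_abs = 2)
  swap <- c(improved = "worsened", same = "same", worsened = "improved")
  expect_identical(unname(swap[pos$category]), neg$category)
  expect_equal(pos$shade, neg$shade)
})

test_that("moving-window smoothing matches the brute-force oracle", {
  expect_equal(smooth_series(c(1, 2, 3, 4, 5), 3, "mean"),
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(smooth_series(c(1, 2, 3), 3, "max"), c(2, 3, 3))
  x <- c(3, NA, 1, 7, NA)
  expect_equal(smooth_series(x, 1, "mean"), x)
  expect_equal(smooth_series(x, 1, "min"), x)
  expect_error(smooth_series(1:5, 2, "mean"), "odd")
  expect_error(smooth_series(1:5, -3, "mean"), "odd")

  set.seed(42)
  for (i in 1:30) {
    x <- rnorm(sample(5:40, 1))
    x[sample(length(x), length(x) %/% 4)] <- NA
    n <- sample(c(1, 3, 5, 7, 9), 1)
    expect_equal(smooth_series(x, n, "mean"), oracle_smooth(x, n, mean))
    expect_equal(smooth_series(x, n, "max"), oracle_smooth(x, n, max))
    expect_equal(smooth_series(x, n, "min"), oracle_smooth(x, n, min))
    # pointwise ordering of the three statistics
    sm <- smooth_series(x, n, "mean"); mx <- smooth_series(x, n, "max")
    mn <- smooth_series(x, n, "min")
    ok <- !is.na(sm)
    expect_true(all(mx[ok] >= sm[ok] & sm[ok] >= mn[ok]))
    # mean smoothing commutes with affine maps
    a <- runif(1, 0.5, 2); b <- rnorm(1)
    expect_equal(smooth_series(a * x + b, n, "mean"),
                 a * smooth_series(x, n, "mean") + b)
  }
})

test_that("improvement profiles categorize every participant per dimension", {
  co <- tiny_cohort(n = 8, n_days = 5)
  prof <- improvement_profiles(co$dataset, eps = 0.1)
  dims <- intersect(coach_dimensions(),
                    unique(co$dataset$variable_specs$dimension))
  expect_setequal(unique(prof$dimension), dims)
  expect_equal(nrow(prof), 8 * length(dims))
  expect_true(all(prof$shade >= 0 & prof$shade <= 1))
  expect_true(all(prof$category[abs(prof$change) <= 0.1] == "same"))
  # the cohort-max change carries shade 1 in its dimension
  for (d in dims) {
    p <- prof[prof$dimension == d, ]
    if (any(p$category != "same")) expect_equal(max(p$shade), 1)
  }
})

test_that("range filtering equals the brute-force subset scan", {
  co <- tiny_cohort(n = 10, n_days = 5)
  prof <- improvement_profiles(co$dataset)

  expect_setequal(filter_by_ranges(prof), unique(prof$participant_id))

  # [0, Inf) on every dimension -> participants with no worsening
  dims <- unique(prof$dimension)
  ranges <- setNames(rep(list(c(0, Inf)), length(dims)), dims)
  got <- filter_by_ranges(prof, ranges)
  wide <- tidyr::pivot_wider(prof[, c("participant_id", "dimension", "change")],
                             names_from = "dimension", values_from = "change")
  expect_setequal(got,
                  wide$participant_id[apply(wide[, dims] >= 0, 1, all)])

  expect_length(filter_by_ranges(prof, list(Physical = c(99, 100))), 0)
  expect_error(filter_by_ranges(prof, list(Physical = c(2, 1))),
               "invalid interval")

  set.seed(43)
  for (i in 1:10) {
    sel <- sample(dims, sample(seq_along(dims), 1))
    ranges <- lapply(setNames(sel, sel), function(d) sort(rnorm(2, sd = 0.5)))
    got <- filter_by_ranges(prof, ranges)
    keep <- unique(prof$participant_id)
    for (d in sel) {
      p <- prof[prof$dimension == d, ]
      keep <- intersect(keep, p$participant_id[
        p$change >= ranges[[d]][1] & p$change <= ranges[[d]][2]])
    }
    expect_setequal(got, keep)
  }
})

test_that("group trajectory views smooth and color member series", {
  co <- tiny_cohort(n = 6, n_days = 12)
  am <- build_activity_matrix(co$dataset)
  prof <- improvement_profiles(co$dataset)

  tv <- group_trajectories(NULL, am, "Nutritional", "Physical", prof,
                           group = "all", n = 3, method = "mean")
  expect_equal(length(unique(tv$participant_id)), 6)
  expect_equal(nrow(tv), 6 * 12)
  # values equal smoothing the raw series directly
  s <- smooth_series(activity_series(am, "P001", "Nutritional"), 3, "mean")
  expect_equal(tv$value[tv$participant_id == "P001"], s)
  # colors come from the color-by dimension's profile
  expect_equal(unique(tv$category[tv$participant_id == "P001"]),
               prof$category[prof$participant_id == "P001" &
                               prof$dimension == "Physical"])

  # singleton group
  lab <- tibble::tibble(participant_id = c("P001", "P002", "P003",
                                           "P004", "P005", "P006"),
                        cluster = c(0L, rep(1L, 5)),
                        outlier_flag = c(TRUE, rep(FALSE, 5)))
  cl <- list(labels = lab, sizes = c("0" = 1L, "1" = 5L))
  class(cl) <- "flat_clustering"
  tv1 <- group_trajectories(cl, am, "Physical", "Physical", prof, group = 0)
  expect_equal(unique(tv1$participant_id), "P001")

  expect_error(group_trajectories(cl, am, "Physical", "Physical", prof,
                                  group = 9), "unknown group")
})
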