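# Independent brute-force oracles used to verify the implementation.

# Exhaustive average-linkage agglomerator: cluster averages recomputed from
# the ORIGINAL distance matrix at every step (no incremental update), same
# deterministic tie-break on creation ids. Returns merge heights and the
# sorted leaf sets merged at each step.
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)  # leaf index sets
  ids <- seq_len(n)                         # creation ids
  heights <- numeric(0)
  sets <- list()
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        avg <- mean(D[clusters[[i]], clusters[[j]]])
        lo <- min(ids[i], ids[j]); hi <- max(ids[i], ids[j])
        if (is.null(best) || avg < best$avg ||
            (avg == best$avg && (lo < best$lo ||
                                 (lo == best$lo && hi < best$hi)))) {
          best <- list(avg = avg, i = i, j = j, lo = lo, hi = hi)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$avg)
    sets[[step]] <- merged
    clusters[[best$i]] <- merged
    ids[best$i] <- n + step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  list(heights = heights, sets = sets)
}

# Leaf sets merged at each step of an hclust-style merge matrix.
merge_sets <- function(tree) {
  n <- length(tree$height) + 1L
  members <- list()
  lapply(seq_len(n - 1), function(s) {
    get_set <- function(code) if (code < 0) -code else members[[code]]
    out <- sort(c(get_set(tree$merge[s, 1]), get_set(tree$merge[s, 2])))
    members[[s]] <<- out
    out
  })
}

# Brute-force centered moving-window statistic with boundary shrink and
# missing-day exclusion.
oracle_smooth <- function(x, n, fun) {
  half <- (n - 1) / 2
  sapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_real_ else fun(w)
  })
}

# Random standardized participant matrix with ids.
random_z <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("P%02d", seq_len(n)),
                         paste0("v", seq_len(p))))
}

# Minimal hand-built cohort: k participants, two timepoints, a few days of
# daily answers, using the default specifications.
tiny_cohort <- function(n = 3, n_days = 10, seed = 42) {
  generate_cohort(synthetic_config(
    n_participants = n, n_days = n_days, seed = seed,
    n_outliers = 0L, missing_rate = 0,
    groups = list(list(proportion = 1, shift = c(),
                       activity = c(Physical = 8, Cognitive = 3,
                                    Social = 6, Nutritional = 10)))))
}
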