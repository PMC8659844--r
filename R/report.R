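# Report pipeline: the two-step analysis workflow as one orchestrated run.
#
# Step 1 reviews the assessment data (per-variable baseline/final histogram
# overlays); step 2 groups participants on the standardized baseline
# assessments and studies in-program activity against pre/post change.
# Every number in the report is computed by the underlying exported
# operations; the pipeline only sequences them and serializes the results.

#' Baseline/final histogram overlay for one assessment variable
#'
#' Bins the two timepoints on shared edges (Freedman-Diaconis rule on the
#' pooled values unless `bins` is given) so the two distributions overlay
#' comparably.
#'
#' @param assessments Assessment tibble (one column per variable id).
#' @param variable Variable id.
#' @param bins Optional number of bins (overrides the automatic rule).
#' @return List with `edges` (bin edges) and `counts` (tibble `timepoint`,
#'   `bin`, `lower`, `upper`, `count`).
#' @export
histogram_overlay <- function(assessments, variable, bins = NULL) {
  if (!variable %in% names(assessments))
    abort_data(paste0("unknown variable '", variable, "'"))
  vals <- list(
    baseline = assessments[[variable]][assessments$timepoint == "baseline"],
    final = assessments[[variable]][assessments$timepoint == "final"])
  vals <- lapply(vals, function(x) x[is.finite(x)])
  pooled <- unlist(vals)
  if (length(pooled) == 0) abort_data("no finite values to bin")
  if (is.null(bins)) {
    # Freedman-Diaconis on the pooled timepoints
    iqr <- stats::IQR(pooled, type = 7)
    h <- 2 * iqr / length(pooled)^(1 / 3)
    bins <- if (h > 0) max(1L, ceiling(diff(range(pooled)) / h)) else 1L
    bins <- min(bins, 100L)
  }
  rng <- range(pooled)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- dplyr::bind_rows(lapply(names(vals), function(tp) {
    x <- vals[[tp]]
    cnt <- if (length(x) == 0) rep(0L, bins) else
      as.integer(table(cut(x, edges, include.lowest = TRUE,
                           labels = FALSE)) [as.character(seq_len(bins))])
    cnt[is.na(cnt)] <- 0L
    tibble::tibble(timepoint = tp, bin = seq_len(bins),
                   lower = edges[-length(edges)], upper = edges[-1],
                   count = cnt)
  }))
  list(edges = edges, counts = counts)
}

#' Run the full analysis pipeline
#'
#' Ingests (or accepts) a cohort dataset and produces the complete report
#' bundle: histogram overlays, robust standardization model, weighted
#' Manhattan average-linkage clustering with a dendrogram cut, cluster
#' sizes/proportions, standardized radar profiles, improvement profiles and
#' smoothed group trajectory views. With `out_dir` set, JSON/CSV exports
#' and static PNG charts are written.
#'
#' @param dataset A `cohort_dataset` (or a list with `assessment_csv` and
#'   `daily_csv` paths to ingest).
#' @param weights Weight configuration list for [resolve_weights()].
#' @param threshold Dendrogram cut threshold (default 0.5).
#' @param mode Threshold mode, `"fraction"` or `"absolute"`.
#' @param min_cluster_size Minimum non-outlier group size (default 3).
#' @param eps "Same state" band half-width for improvement categories.
#' @param smooth_n Odd trajectory smoothing window (default 7).
#' @param smooth_method `"mean"`, `"max"` or `"min"`.
#' @param run_mode `"learning"` adds explanatory text blocks to the report;
#'   `"pro"` omits them.
#' @param out_dir Optional output directory for JSON/CSV/PNG artifacts.
#' @param figures Write PNG charts (default `FALSE`; data exports are
#'   always written when `out_dir` is set).
#' @return The report bundle as a list.
#' @export
run_pipeline <- function(dataset, weights = list(), threshold = 0.5,
                         mode = c("fraction", "absolute"),
                         min_cluster_size = 3L, eps = 0.1, smooth_n = 7L,
                         smooth_method = "mean",
                         run_mode = c("pro", "learning"), out_dir = NULL,
                         figures = FALSE) {
  mode <- match.arg(mode)
  run_mode <- match.arg(run_mode)
  if (!inherits(dataset, "cohort_dataset")) {
    if (!is.list(dataset) || is.null(dataset$assessment_csv))
      abort_data("dataset must be a cohort_dataset or a list of CSV paths")
    assessments <- read_assessment_csv(dataset$assessment_csv)
    daily <- read_daily_csv(dataset$daily_csv)
    dataset <- cohort_dataset(assessments = assessments, daily = daily)
  }

  base <- dataset$assessments[dataset$assessments$timepoint == "baseline", ]
  model <- fit_standardization(base)
  vars <- model$variable[!model$degenerate]

  histograms <- lapply(stats::setNames(vars, vars), function(v)
    histogram_overlay(dataset$assessments, v))

  Z <- participant_vectors(dataset, model)
  w <- resolve_weights(weights, dataset$variable_specs)
  D <- pairwise_distances(Z, w[colnames(Z)])
  tree <- agglomerate_average(D)
  clustering <- cut_dendrogram(tree, threshold = threshold, mode = mode,
                               min_cluster_size = min_cluster_size)
  profiles_radar <- cluster_profiles(clustering, Z, dataset$variable_specs)

  am <- build_activity_matrix(dataset)
  improvement <- improvement_profiles(dataset, model, eps = eps)
  main_groups <- as.integer(names(clustering$sizes)[!clustering$outlier_flags])
  trajectories <- list()
  for (g in main_groups) {
    for (d in intersect(COACH_DIMENSIONS, unique(am$dimension))) {
      key <- paste0("group", g, "_", tolower(d))
      trajectories[[key]] <- group_trajectories(
        clustering, am, activity_dim = d,
        color_dim = improvement$dimension[1], improvement, group = g,
        n = smooth_n, method = smooth_method)
    }
  }

  report <- list(
    run_mode = run_mode,
    parameters = list(threshold = threshold, mode = mode,
                      min_cluster_size = min_cluster_size, eps = eps,
                      smooth_n = smooth_n, smooth_method = smooth_method,
                      weights = as.list(w)),
    n_participants = length(participants(dataset)),
    histograms = lapply(histograms, function(h)
      list(edges = h$edges, counts = h$counts)),
    standardization = tibble::as_tibble(model),
    clustering = list(
      sizes = as.list(clustering$sizes),
      proportions = as.list(clustering$proportions),
      outlier_groups = as.list(clustering$outlier_flags),
      threshold_used = clustering$threshold_used,
      labels = clustering$labels),
    radar_profiles = profiles_radar,
    improvement = tibble::as_tibble(improvement)
  )
  if (run_mode == "learning") {
    report$notes <- list(
      histograms = paste("Each variable is shown as two overlaid",
                         "distributions: baseline and final assessment.",
                         "A rightward shift of an oriented variable",
                         "suggests cohort-level improvement."),
      clustering = paste("Participants are grouped by weighted Manhattan",
                         "distance on standardized baseline assessments",
                         "using average linkage; cutting the dendrogram at",
                         "the chosen dissimilarity yields the groups.",
                         "Very small groups are outliers and excluded",
                         "from insight extraction."),
      evolution = paste("Trajectory views show smoothed daily activity",
                        "per group, colored green/yellow/red by each",
                        "member's assessment improvement, with darker",
                        "shades for larger changes."))
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_summary_json(report[setdiff(names(report),
                                      c("histograms"))],
                       file.path(out_dir, "report.json"))
    write_standardization_json(model,
                               file.path(out_dir, "standardization.json"))
    readr::write_csv(clustering$labels, file.path(out_dir, "clusters.csv"),
                     progress = FALSE)
    write_dendrogram_json(tree, file.path(out_dir, "dendrogram.json"))
    write_dendrogram_newick(tree, file.path(out_dir, "dendrogram.nwk"))
    write_activity_csv(am, file.path(out_dir, "activity.csv"))
    write_profiles_csv(improvement, file.path(out_dir, "improvement.csv"))
    readr::write_csv(profiles_radar, file.path(out_dir, "radar.csv"),
                     progress = FALSE)
    traj_long <- dplyr::bind_rows(lapply(names(trajectories), function(k) {
      tv <- trajectories[[k]]
      tibble::tibble(view = k, activity_dim = attr(tv, "activity_dim"),
                     participant_id = tv$participant_id,
                     day_index = tv$day_index, value = tv$value,
                     category = tv$category, shade = tv$shade)
    }))
    readr::write_csv(traj_long, file.path(out_dir, "trajectories.csv"),
                     progress = FALSE)
    if (figures) write_report_figures(report, tree, trajectories, out_dir)
  }

  report$trajectories <- trajectories
  invisible(report)
}

# Static PNG charts for a report bundle. Figures mirror the CSV/JSON data
# exports one-to-one; nothing is computed here.
write_report_figures <- function(report, tree, trajectories, out_dir) {
  vars <- names(report$histograms)[seq_len(min(4, length(report$histograms)))]
  for (v in vars) {
    h <- report$histograms[[v]]
    p <- ggplot2::ggplot(h$counts,
                         ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                      y = .data$count,
                                      fill = .data$timepoint)) +
      ggplot2::geom_col(position = "identity", alpha = 0.55) +
      ggplot2::scale_fill_manual(values = c(baseline = "#1f77b4",
                                            final = "#ff7f0e")) +
      ggplot2::labs(x = v, y = "participants",
                    title = paste0(v, ": baseline vs final")) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, paste0("hist_", v, ".png")), p,
                    width = 6, height = 4, dpi = 120)
  }
  grDevices::png(file.path(out_dir, "dendrogram.png"), width = 900,
                 height = 500)
  plot(stats::as.hclust(tree), hang = -1, cex = 0.6,
       main = "Participant dendrogram (average linkage)",
       xlab = "", sub = "", ylab = "dissimilarity")
  grDevices::dev.off()

  sizes <- tibble::tibble(cluster = names(report$clustering$sizes),
                          n = unlist(report$clustering$sizes))
  p <- ggplot2::ggplot(sizes, ggplot2::aes(x = "", y = .data$n,
                                           fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) + ggplot2::coord_polar("y") +
    ggplot2::labs(title = "Group sizes") + ggplot2::theme_void()
  ggplot2::ggsave(file.path(out_dir, "pie.png"), p, width = 5, height = 5,
                  dpi = 120)

  radar <- report$radar_profiles
  p <- ggplot2::ggplot(radar, ggplot2::aes(x = .data$variable,
                                           y = .data$mean_z,
                                           group = factor(.data$cluster),
                                           color = factor(.data$cluster))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(title = "Standardized group profiles", color = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
  ggplot2::ggsave(file.path(out_dir, "radar.png"), p, width = 7, height = 6,
                  dpi = 120)

  imp <- report$improvement
  p <- ggplot2::ggplot(imp, ggplot2::aes(x = .data$dimension,
                                         y = .data$change,
                                         group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(title = "Per-participant change across dimensions",
                  y = "standardized change") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "parallel.png"), p, width = 6,
                  height = 4, dpi = 120)

  if (length(trajectories) > 0) {
    tv <- trajectories[[1]]
    p <- ggplot2::ggplot(tv, ggplot2::aes(x = .data$day_index,
                                          y = .data$value,
                                          group = .data$participant_id,
                                          color = .data$category,
                                          alpha = .data$shade)) +
      ggplot2::geom_line() +
      ggplot2::scale_color_manual(values = c(improved = "#2ca02c",
                                             same = "#bcbd22",
                                             worsened = "#d62728"),
                                  na.value = "grey60") +
      ggplot2::labs(title = paste0("Smoothed ", attr(tv, "activity_dim"),
                                   " activity, colored by ",
                                   attr(tv, "color_dim"), " improvement"),
                    x = "day", y = "activity level") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, "evolution.png"), p, width = 7,
                    height = 4, dpi = 120)
  }
  invisible(out_dir)
}
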