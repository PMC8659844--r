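# Participant similarity and average-linkage agglomeration.
#
# Participants are compared on their standardized baseline assessment
# vectors with a weighted Manhattan distance,
#
#   d(u, v) = sum_i w_i * |u_i - v_i| ,  w_i in {0, 0.5, 1, 1.5, 2},
#
# and grouped by hierarchical agglomerative clustering with average linkage
# (UPGMA): at every step the pair of clusters with the smallest mean
# pairwise inter-cluster distance is merged, and the recorded merge height
# is that mean. Cutting the resulting dendrogram at a dissimilarity
# threshold yields a flat grouping; groups below a minimum size are flagged
# as outlier groups and excluded from insight extraction.

#' Standardized baseline participant vectors
#'
#' @param dataset A `cohort_dataset`.
#' @param model A `standardization_model` (defaults to a model fitted on the
#'   dataset's baseline assessments).
#' @return Numeric matrix, participants x non-degenerate variables, of
#'   baseline z-scores (rownames = participant ids).
#' @export
participant_vectors <- function(dataset, model = NULL) {
  base <- dataset$assessments[dataset$assessments$timepoint == "baseline", ]
  if (nrow(base) == 0) abort_data("no baseline assessments")
  if (is.null(model)) model <- fit_standardization(base)
  vars <- model$variable[!model$degenerate]
  if (length(vars) == 0) abort_data("all variables degenerate")
  Z <- sapply(vars, function(v) standardize(model, v, base[[v]]))
  Z <- matrix(Z, nrow = nrow(base), dimnames = list(base$participant_id, vars))
  Z
}

#' Weighted Manhattan distance between two participants
#'
#' `d(u, v) = sum_i w_i |u_i - v_i|` over the variables both participants
#' have. When some variables are missing in one of the two vectors, the sum
#' over the shared variables is rescaled by (total weight)/(shared weight)
#' so distances stay comparable across pairs.
#'
#' @param u,v Named numeric vectors of standardized values.
#' @param w Named nonnegative weight vector (defaults to 1 per variable).
#' @return Nonnegative distance.
#' @export
weighted_manhattan <- function(u, v, w = NULL) {
  vars <- intersect(names(u), names(v))
  if (length(vars) == 0) abort_data("no shared variables between vectors")
  if (is.null(w)) w <- stats::setNames(rep(1, length(vars)), vars)
  if (any(w < 0)) abort_data("weights must be nonnegative")
  vars <- intersect(vars, names(w))
  if (length(vars) == 0) abort_data("no shared weighted variables")
  uu <- u[vars]; vv <- v[vars]; ww <- w[vars]
  shared <- !is.na(uu) & !is.na(vv)
  total_w <- sum(ww)
  shared_w <- sum(ww[shared])
  if (!any(shared) || (total_w > 0 && shared_w == 0))
    abort_data("no shared observed variables between vectors")
  d <- sum(ww[shared] * abs(uu[shared] - vv[shared]))
  if (total_w > 0) d <- d * total_w / shared_w
  d
}

#' Pairwise weighted Manhattan distance matrix
#'
#' @param Z Numeric matrix, participants x variables (rownames = ids).
#' @param w Named nonnegative weight vector over the matrix columns
#'   (defaults to 1 per variable).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(Z, w = NULL) {
  if (nrow(Z) < 2) abort_data("need at least 2 participants")
  vars <- colnames(Z)
  if (is.null(w)) w <- stats::setNames(rep(1, ncol(Z)), vars)
  w <- w[vars]
  if (anyNA(w)) abort_data("weight vector does not cover all variables")
  if (any(w < 0)) abort_data("weights must be nonnegative")
  n <- nrow(Z)
  obs <- !is.na(Z)
  total_w <- sum(w)
  D <- matrix(0, n, n, dimnames = list(rownames(Z), rownames(Z)))
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    diff <- abs(sweep(Z[idx, , drop = FALSE], 2, Z[i, ], "-"))
    contrib <- sweep(diff, 2, w, "*")
    d <- rowSums(contrib, na.rm = TRUE)
    shared_w <- (obs[idx, , drop = FALSE] *
                   rep(obs[i, ], each = length(idx))) %*% w
    if (any(shared_w == 0 & total_w > 0))
      abort_data("participant pair with no shared observed variables")
    if (total_w > 0) d <- d * total_w / as.numeric(shared_w)
    D[i, idx] <- d
    D[idx, i] <- d
  }
  D
}

#' Average-linkage agglomeration (UPGMA)
#'
#' Repeatedly merges the pair of clusters with the minimal average
#' inter-cluster distance; the recorded height is that average. Ties are
#' broken deterministically on the lowest pair of cluster creation ids
#' (singletons are numbered in input order, merged clusters in merge
#' order), so the merge sequence is reproducible and oracle-matchable.
#'
#' @param D Symmetric distance matrix with finite entries and zero diagonal.
#' @return An object of class `c("coach_tree", "hclust")`: components
#'   `merge`, `height`, `order`, `labels`, usable with [stats::cutree()] and
#'   convertible with [ape::as.phylo()].
#' @export
agglomerate_average <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) abort_data("need at least 2 elements to agglomerate")
  if (any(!is.finite(D))) abort_data("non-finite distance entries")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    abort_data("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(D) %||% as.character(seq_len(n))

  # active cluster bookkeeping: creation id (1..n singletons, n+step after a
  # merge), size, and the hclust merge-matrix code (-leaf or +merge-row)
  d <- D
  active <- seq_len(n)           # positions in `d` currently in use
  id <- seq_len(n)               # creation id per position
  size <- rep(1L, n)
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- NULL
    for (ai in seq_len(m - 1)) {
      for (aj in (ai + 1):m) {
        pi <- active[ai]; pj <- active[aj]
        dij <- d[pi, pj]
        key_lo <- min(id[pi], id[pj]); key_hi <- max(id[pi], id[pj])
        if (is.null(best) || dij < best$d ||
            (dij == best$d && (key_lo < best$lo ||
                               (key_lo == best$lo && key_hi < best$hi)))) {
          best <- list(d = dij, i = pi, j = pj, lo = key_lo, hi = key_hi)
        }
      }
    }
    pi <- best$i; pj <- best$j
    merge[step, ] <- sort(c(code[pi], code[pj]))
    height[step] <- best$d
    # average-linkage update (Lance-Williams): size-weighted mean keeps the
    # entry equal to the mean over all original cross-cluster pairs
    others <- setdiff(active, c(pi, pj))
    if (length(others) > 0) {
      newd <- (size[pi] * d[pi, others] + size[pj] * d[pj, others]) /
        (size[pi] + size[pj])
      d[pi, others] <- newd
      d[others, pi] <- newd
    }
    size[pi] <- size[pi] + size[pj]
    id[pi] <- n + step
    code[pi] <- step
    active <- setdiff(active, pj)
  }

  tree <- list(merge = merge, height = height,
               order = leaf_order(merge, n), labels = labels,
               method = "average", dist.method = "weighted_manhattan",
               call = match.call())
  class(tree) <- c("coach_tree", "hclust")
  tree
}

# left-to-right leaf ordering by depth-first traversal of the merge matrix
leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Cut a dendrogram into a flat clustering
#'
#' Clusters are the connected leaf sets whose merges lie at or below the cut
#' height. The threshold is interpreted either as a fraction of the maximum
#' merge height (default; a normalized dissimilarity in (0, 1]) or as an
#' absolute height; alternatively an exact number of clusters `k` can be
#' requested. Cluster ids are assigned by decreasing size (cluster 0 is the
#' largest); clusters smaller than `min_cluster_size` are flagged as
#' outlier groups.
#'
#' @param tree A tree from [agglomerate_average()] (or any `hclust`).
#' @param threshold Cut threshold (ignored when `k` is given).
#' @param mode `"fraction"` (of the maximum merge height) or `"absolute"`.
#' @param k Optional exact number of clusters.
#' @param min_cluster_size Minimum size of a non-outlier group (default 3).
#' @return An object of class `flat_clustering`: `labels` (tibble
#'   `participant_id`, `cluster`, `outlier_flag`), `sizes`, `proportions`,
#'   `outlier_flags`, `threshold_used`, `mode`.
#' @export
cut_dendrogram <- function(tree, threshold = NULL,
                           mode = c("fraction", "absolute"),
                           k = NULL, min_cluster_size = 3L) {
  mode <- match.arg(mode)
  if (is.null(k)) {
    if (is.null(threshold) || !is.finite(threshold) || threshold <= 0)
      abort_data("cut threshold must be a positive number")
    h <- switch(mode,
      fraction = {
        if (threshold > 1)
          abort_data("fraction-mode threshold must be in (0, 1]")
        threshold * max(tree$height)
      },
      absolute = threshold)
    raw <- stats::cutree(tree, h = h)
    used <- h
  } else {
    if (k < 1 || k > length(tree$labels)) abort_data("invalid cluster count k")
    raw <- stats::cutree(tree, k = k)
    used <- NA_real_
  }
  relabel_clustering(raw, min_cluster_size, used, mode)
}

relabel_clustering <- function(raw, min_cluster_size, threshold_used, mode) {
  tab <- table(raw)
  first_seen <- vapply(names(tab), function(g) min(which(raw == g)),
                       numeric(1))
  ord <- order(-as.integer(tab), first_seen)
  new_ids <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  cluster <- unname(new_ids[as.character(raw)])
  sizes <- as.integer(tab[names(tab)[ord]])
  names(sizes) <- as.character(seq_along(ord) - 1L)
  proportions <- sizes / length(raw)
  outlier_flags <- sizes < min_cluster_size
  labels <- tibble::tibble(
    participant_id = names(raw) %||% as.character(seq_along(raw)),
    cluster = cluster,
    outlier_flag = unname(outlier_flags[as.character(cluster)]))
  structure(
    list(labels = labels, sizes = sizes, proportions = proportions,
         outlier_flags = outlier_flags, threshold_used = threshold_used,
         mode = mode, min_cluster_size = min_cluster_size),
    class = "flat_clustering")
}

#' @export
print.flat_clustering <- function(x, ...) {
  cat("<flat_clustering> ", length(x$sizes), " clusters over ",
      sum(x$sizes), " participants\n", sep = "")
  for (g in names(x$sizes)) {
    cat("  Group ", g, ": n = ", x$sizes[[g]], " (",
        sprintf("%.1f%%", 100 * x$proportions[[g]]),
        if (x$outlier_flags[[g]]) ", outlier group" else "", ")\n", sep = "")
  }
  invisible(x)
}

#' Per-cluster mean standardized assessment profiles
#'
#' Radar-chart data: the mean standardized baseline value of every variable
#' of the selected coaching dimensions, per cluster.
#'
#' @param clustering A `flat_clustering`.
#' @param Z Standardized participant matrix from [participant_vectors()].
#' @param variable_specs Assessment-variable specification tibble.
#' @param dimensions Coaching dimensions to include (default all four).
#' @return Tibble: `cluster`, `variable`, `dimension`, `mean_z`.
#' @export
cluster_profiles <- function(clustering, Z,
                             variable_specs = default_variable_specs(),
                             dimensions = COACH_DIMENSIONS) {
  if (length(dimensions) == 0) abort_data("empty dimension selection")
  bad <- setdiff(dimensions, COACH_DIMENSIONS)
  if (length(bad) > 0)
    abort_data(paste0("unknown dimension(s): ", paste(bad, collapse = ", ")))
  vars <- variable_specs$id[variable_specs$dimension %in% dimensions]
  vars <- intersect(vars, colnames(Z))
  if (length(vars) == 0) abort_data("no variables in the selected dimensions")
  lab <- clustering$labels
  rows <- lapply(sort(unique(lab$cluster)), function(g) {
    members <- lab$participant_id[lab$cluster == g]
    zm <- Z[members, vars, drop = FALSE]
    tibble::tibble(cluster = g, variable = vars,
                   dimension = variable_specs$dimension[
                     match(vars, variable_specs$id)],
                   mean_z = unname(colMeans(zm, na.rm = TRUE)))
  })
  dplyr::bind_rows(rows)
}

#' Export a dendrogram as a JSON merge list
#'
#' @param tree A tree from [agglomerate_average()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_json <- function(tree, path) {
  merges <- lapply(seq_along(tree$height), function(i) {
    list(left = tree$merge[i, 1], right = tree$merge[i, 2],
         height = tree$height[i])
  })
  jsonlite::write_json(list(labels = tree$labels, merges = merges), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a dendrogram in Newick format with branch lengths
#'
#' @param tree A tree from [agglomerate_average()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @export
as.hclust.coach_tree <- function(x, ...) {
  class(x) <- "hclust"
  x
}
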