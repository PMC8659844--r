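test_that("weighted Manhattan distance matches hand evaluation", {
  u <- c(a = 1, b = 0); v <- c(a = 0, b = 2)
  expect_equal(weighted_manhattan(u, v, c(a = 1, b = 0.5)), 1 * 1 + 0.5 * 2)
  expect_equal(weighted_manhattan(u, u, c(a = 1, b = 0.5)), 0)
  expect_equal(weighted_manhattan(u, v, c(a = 0, b = 0)), 0)
  expect_error(weighted_manhattan(c(a = 1), c(b = 1)), "no shared")
  expect_error(weighted_manhattan(u, v, c(a = -1, b = 1)), "nonnegative")
})

test_that("pairwise distances form a weighted L1 metric", {
  # 3 points on a line, unit weight -> absolute differences
  Z <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  D <- pairwise_distances(Z)
  expect_equal(D["A", "B"], 1)
  expect_equal(D["A", "C"], 10)
  expect_equal(D["B", "C"], 9)

  set.seed(31)
  Z <- random_z(12, 5)
  w <- setNames(sample(c(0, 0.5, 1, 1.5, 2), 5, replace = TRUE), colnames(Z))
  if (sum(w) == 0) w[1] <- 1
  D <- pairwise_distances(Z, w)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # triangle inequality over all triples
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  # agreement with the pairwise scalar form
  expect_equal(D[3, 7], weighted_manhattan(Z[3, ], Z[7, ], w))
})

test_that("missing variables use pairwise deletion with weight rescaling", {
  u <- c(a = 1, b = NA, c = 0); v <- c(a = 0, b = 5, c = 2)
  w <- c(a = 1, b = 1, c = 2)
  # shared weight 3 of total 4 -> rescale by 4/3
  expect_equal(weighted_manhattan(u, v, w), (1 * 1 + 2 * 2) * 4 / 3)
  Z <- rbind(u, v)
  colnames(Z) <- names(u); rownames(Z) <- c("u", "v")
  D <- pairwise_distances(Z, w)
  expect_equal(D["u", "v"], (1 * 1 + 2 * 2) * 4 / 3)
})

test_that("average-linkage merges follow the hand-built example", {
  Z <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  tree <- agglomerate_average(pairwise_distances(Z))
  expect_equal(tree$height, c(1, (10 + 9) / 2))

  # n = 2: single merge at the pairwise distance
  Z2 <- matrix(c(0, 3), 2, 1, dimnames = list(c("A", "B"), "x"))
  tree2 <- agglomerate_average(pairwise_distances(Z2))
  expect_equal(tree2$height, 3)

  D <- pairwise_distances(Z)
  D[1, 2] <- Inf
  expect_error(agglomerate_average(D), "symmetric|non-finite")
})

test_that("merge heights and order match the brute-force agglomerator", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    Z <- random_z(n, sample(2:4, 1))
    D <- pairwise_distances(Z)
    tree <- agglomerate_average(D)
    oracle <- oracle_upgma(D)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    sets <- lapply(merge_sets(tree), function(s) sort(rownames(D)[s]))
    osets <- lapply(oracle$sets, function(s) sort(rownames(D)[s]))
    expect_identical(sets, osets)
  }
  # independent library cross-check on the sorted heights
  Z <- random_z(15, 4, seed = 33)
  D <- pairwise_distances(Z)
  ours <- agglomerate_average(D)
  ref <- stats::hclust(stats::as.dist(D), method = "average")
  expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-10)
})

test_that("dendrogram cuts behave monotonically and flag outlier groups", {
  Z <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  tree <- agglomerate_average(pairwise_distances(Z))

  all_one <- cut_dendrogram(tree, threshold = 1, mode = "fraction",
                            min_cluster_size = 1)
  expect_equal(length(all_one$sizes), 1L)
  expect_equal(unname(all_one$sizes), 3L)

  singles <- cut_dendrogram(tree, threshold = 0.5, mode = "absolute",
                            min_cluster_size = 1)
  expect_equal(length(singles$sizes), 3L)

  mid <- cut_dendrogram(tree, threshold = 5, mode = "absolute",
                        min_cluster_size = 2)
  expect_equal(length(mid$sizes), 2L)
  members <- split(mid$labels$participant_id, mid$labels$cluster)
  expect_setequal(members[["0"]], c("A", "B"))
  expect_setequal(members[["1"]], "C")
  expect_true(mid$outlier_flags[["1"]])   # size 1 < min_cluster_size 2
  expect_false(mid$outlier_flags[["0"]])
  expect_equal(sum(mid$proportions), 1)

  expect_error(cut_dendrogram(tree, threshold = 0), "positive")
  expect_error(cut_dendrogram(tree, threshold = 2, mode = "fraction"),
               "in \\(0, 1\\]")

  # monotone: cluster count non-increasing in the threshold
  set.seed(34)
  Zr <- random_z(20, 4)
  tr <- agglomerate_average(pairwise_distances(Zr))
  counts <- vapply(seq(0.05, 1, by = 0.05), function(th)
    length(cut_dendrogram(tr, threshold = th)$sizes), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("scaling the weights scales heights but not the flat clustering", {
  set.seed(35)
  Z <- random_z(15, 5)
  w <- setNames(c(0.5, 1, 1.5, 2, 1), colnames(Z))
  t1 <- agglomerate_average(pairwise_distances(Z, w))
  t2 <- agglomerate_average(pairwise_distances(Z, 3 * w))
  expect_equal(t2$height, 3 * t1$height, tolerance = 1e-12)
  c1 <- cut_dendrogram(t1, threshold = 0.6)
  c2 <- cut_dendrogram(t2, threshold = 0.6)
  expect_equal(c1$labels$cluster, c2$labels$cluster)
})

test_that("cluster ids are assigned by decreasing size", {
  set.seed(36)
  Z <- rbind(random_z(8, 3) + 5, random_z(3, 3) - 5)
  rownames(Z) <- sprintf("P%02d", 1:11)
  tree <- agglomerate_average(pairwise_distances(Z))
  cl <- cut_dendrogram(tree, k = 2)
  expect_equal(unname(cl$sizes), sort(unname(cl$sizes), decreasing = TRUE))
  expect_equal(names(cl$sizes), c("0", "1"))
  expect_equal(unname(cl$sizes[["0"]]), 8L)
})

# flat clustering built directly from the generator's planted labels
relabel_from_truth <- function(co) {
  g <- co$truth$groups
  raw <- setNames(g$group, g$participant_id)
  cohortcoach:::relabel_clustering(raw, min_cluster_size = 3,
                                   threshold_used = NA_real_,
                                   mode = "fraction")
}

test_that("cluster profiles average standardized values per cluster", {
  set.seed(37)
  co <- tiny_cohort(n = 10, n_days = 3)
  Z <- participant_vectors(co$dataset)
  tree <- agglomerate_average(pairwise_distances(Z))
  vs <- co$dataset$variable_specs

  # singleton cluster -> its own z-vector
  singles <- cut_dendrogram(tree, threshold = 1e-9, mode = "absolute",
                            min_cluster_size = 1)
  prof <- cluster_profiles(singles, Z, vs, dimensions = "Cognitive")
  p1 <- singles$labels$participant_id[singles$labels$cluster == 0][1]
  expect_equal(prof$mean_z[prof$cluster == 0],
               unname(Z[p1, c("moca", "mcs_a", "mai")]))

  # the all-participants cluster is ~0: standardization centers the cohort
  # (exactly 0 on the Tukey-clean subset; a few excluded tail values can
  # bias the all-member mean by at most ~|z|_max/n)
  co_big <- tiny_cohort(n = 40, n_days = 3)
  Zb <- participant_vectors(co_big$dataset)
  tree_b <- agglomerate_average(pairwise_distances(Zb))
  one <- cut_dendrogram(tree_b, threshold = 1, min_cluster_size = 1)
  prof1 <- cluster_profiles(one, Zb, vs)
  expect_true(all(abs(prof1$mean_z) < 0.3))

  # planted mean shift separates the profiles in the shifted variable
  co2 <- generate_cohort(synthetic_config(
    n_participants = 20, n_days = 3, seed = 5, n_outliers = 0,
    missing_rate = 0,
    groups = list(
      list(proportion = 0.5, shift = c(mna_mini = -2),
           activity = c(Physical = 8, Cognitive = 3, Social = 6,
                        Nutritional = 10)),
      list(proportion = 0.5, shift = c(mna_mini = 2),
           activity = c(Physical = 8, Cognitive = 3, Social = 6,
                        Nutritional = 10)))))
  Z2 <- participant_vectors(co2$dataset)
  truth_cl <- relabel_from_truth(co2)
  prof2 <- cluster_profiles(truth_cl, Z2, vs, dimensions = "Nutritional")
  gap <- abs(diff(prof2$mean_z[prof2$variable == "mna_mini"]))
  # planted raw-z separation 4; the two-group mixture has sd sqrt(1 + 2^2),
  # so the standardized separation is ~4/2.24 = 1.79 minus sampling noise
  expect_gt(gap, 1.2)

  expect_error(cluster_profiles(singles, Z, vs, dimensions = character()),
               "empty")
})

test_that("dendrograms export to JSON and Newick", {
  Z <- random_z(6, 3, seed = 38)
  tree <- agglomerate_average(pairwise_distances(Z))
  dir <- withr::local_tempdir()
  write_dendrogram_json(tree, file.path(dir, "d.json"))
  j <- jsonlite::read_json(file.path(dir, "d.json"), simplifyVector = TRUE)
  expect_equal(j$merges$height, tree$height)
  write_dendrogram_newick(tree, file.path(dir, "d.nwk"))
  phy <- ape::read.tree(file.path(dir, "d.nwk"))
  expect_setequal(phy$tip.label, rownames(Z))
})
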