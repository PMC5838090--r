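test_that("replicate merging concatenates and keeps replicate identity", {
  mk <- function(n, rep) data.frame(trajectory_id = sprintf("t%02d", 1:n),
                                    volume_nl = runif(n, 0.1, 2),
                                    velocity_ms = runif(n, 1, 5),
                                    replicate_id = rep, volume_flagged = FALSE)
  set.seed(1)
  m <- merge_replicates(list(mk(10, "r1"), mk(12, "r2"), mk(8, "r3")))
  expect_equal(nrow(m), 30)
  expect_equal(as.vector(table(m$replicate_id)), c(10, 12, 8))
  # duplicate trajectory ids across replicates stay distinguishable
  expect_equal(anyDuplicated(paste(m$replicate_id, m$trajectory_id)), 0)
  one <- mk(5, "r1")
  expect_identical(merge_replicates(list(one)), one)
  expect_error(merge_replicates(list()), "no droplet records")
})

test_that("k = 1 clustering returns the feature means", {
  rec <- sample_records(list(group_spec("a", 1, 0.3, 3, 0.5, 1)), 40, seed = 2)
  fit <- cluster_droplets(rec, 1, seed = 2)
  expect_equal(fit$cluster, rep(1L, 40))
  expect_equal(as.numeric(fit$centers_std), c(0, 0), tolerance = 1e-9)
})

test_that("two separated populations are assigned to their generating groups", {
  ref <- reference_spray_groups(3.0)
  rec <- sample_records(ref$groups, c(140, 60), seed = 3)
  truth <- rep(1:2, c(140, 60))
  fit <- cluster_droplets(rec, 2, seed = 3)
  # align labels by majority
  map <- as.integer(names(sort(table(fit$cluster[truth == 1]),
                               decreasing = TRUE)))[1]
  agreement <- mean((fit$cluster == map) == (truth == 1))
  expect_gte(agreement, 0.99)
})

test_that("clustering is deterministic for a fixed seed and insensitive to row order", {
  ref <- reference_spray_groups(3.0)
  rec <- sample_records(ref$groups, c(80, 40), seed = 4)
  f1 <- cluster_droplets(rec, 2, seed = 9)
  f2 <- cluster_droplets(rec, 2, seed = 9)
  expect_identical(f1$cluster, f2$cluster)
  expect_equal(f1$tot_withinss, f2$tot_withinss, tolerance = 1e-12)
  # permuted rows, then sorted back: identical centroids
  perm <- sample(seq_len(nrow(rec)))
  rec_p <- rec[perm, ]
  f3 <- cluster_droplets(rec_p[order(perm), ], 2, seed = 9)
  expect_equal(sort(f3$centers_std[, 1]), sort(f1$centers_std[, 1]),
               tolerance = 1e-9)
})

test_that("silhouette-guided selection finds the generative cluster count", {
  # two separated groups
  ref <- reference_spray_groups(3.0)
  rec2 <- sample_records(ref$groups, c(150, 60), seed = 5)
  expect_equal(select_k(rec2, seed = 5)$k, 2)
  # a single population triggers the weak-structure rule
  rec1 <- sample_records(list(group_spec("a", 1, 0.4, 3, 0.8, 1)), 120, seed = 6)
  sel1 <- select_k(rec1, seed = 6)
  expect_equal(sel1$k, 1)
  expect_lt(max(sel1$mean_silhouette), 0.5)
  # three well-separated populations
  g3 <- list(group_spec("a", 0.1, 0.02, 2, 0.3, 0.2),
             group_spec("b", 1.5, 0.3, 3, 0.4, 0.5),
             group_spec("c", 0.3, 0.05, 14, 1.5, 0.3))
  rec3 <- sample_records(g3, c(80, 80, 60), seed = 7)
  expect_equal(select_k(rec3, seed = 7)$k, 3)
  expect_error(select_k(rec3[1:2, ]), "at least 3")
})

test_that("our mean silhouette agrees with a first-principles computation", {
  ref <- reference_spray_groups(3.0)
  rec <- sample_records(ref$groups, c(30, 20), seed = 8)
  x <- spraymode:::cluster_features(rec)
  fit <- cluster_droplets(rec, 2, seed = 8)
  expect_equal(spraymode:::mean_silhouette(x, fit$cluster),
               naive_mean_silhouette(x, fit$cluster), tolerance = 1e-12)
})

test_that("best-of-restarts k-means attains the exhaustive optimum on small instances", {
  set.seed(909)
  wins <- 0; total <- 30
  for (i in 1:total) {
    n <- sample(8:10, 1); k <- sample(2:3, 1)
    rec <- data.frame(trajectory_id = sprintf("t%02d", 1:n),
                      volume_nl = exp(rnorm(n, 0, 1)),
                      velocity_ms = exp(rnorm(n, 1, 0.5)),
                      replicate_id = "r1", volume_flagged = FALSE)
    x <- spraymode:::cluster_features(rec)
    fit <- cluster_droplets(rec, k, seed = i)
    opt <- exhaustive_kmeans_wcss(x, k)
    if (fit$tot_withinss <= opt * (1 + 1e-8)) wins <- wins + 1
  }
  expect_gte(wins / total, 0.95)
})

test_that("group statistics reproduce fractions, ordering and totals", {
  rec <- data.frame(trajectory_id = sprintf("t%02d", 1:6),
                    volume_nl = c(1, 2, 3, 10, 20, 15),
                    velocity_ms = c(3, 3.5, 2.5, 14, 15, 13),
                    replicate_id = "r1", volume_flagged = FALSE)
  res <- group_stats(rec, c(1, 1, 1, 2, 2, 2))
  expect_s3_class(res, "spray_mode_result")
  g <- res$groups
  expect_equal(g$group, 1:2)
  expect_true(all(diff(g$volume_fraction_pct) <= 0))  # descending dominance
  expect_equal(sum(g$volume_fraction_pct), 100, tolerance = 1e-9)
  expect_equal(sum(g$group_volume_nl), sum(rec$volume_nl))
  expect_equal(g$n[1], 3)
  expect_equal(g$volume_mean_nl[1], 15)
  expect_equal(g$velocity_sd_ms[2], sd(c(3, 3.5, 2.5)))
  # single group
  res1 <- group_stats(rec, rep(1, 6))
  expect_equal(res1$groups$volume_fraction_pct, 100)
})

test_that("fraction arithmetic matches the reference group volumes", {
  expect_equal(round(volume_fractions(c(1040, 51))), c(95, 5))
  expect_equal(round(volume_fractions(c(611, 107, 724))), c(42, 7, 50))
  expect_equal(round(volume_fractions(c(833, 179))), c(82, 18))
  # unit invariance: pl vs nl
  v <- c(611, 107, 724)
  expect_equal(volume_fractions(v), volume_fractions(1000 * v))
  expect_error(volume_fractions(c(-1, 2)))
})

test_that("k must not exceed the number of records", {
  rec <- sample_records(list(group_spec("a", 1, 0.3, 3, 0.5, 1)), 4, seed = 10)
  expect_error(cluster_droplets(rec, 5, seed = 1), "cannot form")
  expect_error(cluster_droplets(rec, 0, seed = 1))
})
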