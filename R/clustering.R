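# Spray-mode grouping: merge replicate droplet records, cluster them in
# (volume, velocity) space with Lloyd's k-means under silhouette-guided
# selection of k, and summarize group centroids, group volumes and
# fractional volume contributions.

#' Merge replicate droplet record sets
#'
#' Concatenates the droplet records of independently analysed image
#' sequences (typically three per parameter set) into one data set for
#' clustering, preserving each record's `replicate_id`.
#'
#' @param record_sets A list of record data.frames ([make_records()] output).
#' @return One combined record data.frame.
#' @export
merge_replicates <- function(record_sets) {
  if (is.data.frame(record_sets)) record_sets <- list(record_sets)
  if (length(record_sets) == 0 || sum(vapply(record_sets, nrow, 0L)) == 0)
    stop("no droplet records to merge")
  out <- do.call(rbind, record_sets)
  rownames(out) <- NULL
  out
}

# feature matrix for clustering: z-scored (volume, velocity), optionally on
# log volumes
cluster_features <- function(records, transform = c("log_volume", "identity")) {
  transform <- match.arg(transform)
  v <- records$volume_nl
  if (transform == "log_volume") v <- log(v)
  x <- cbind(volume = v, velocity = records$velocity_ms)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1          # degenerate axis: centre only
  scale(x, center = colMeans(x), scale = s)
}

# k-means++-style seeding: spread the initial centres out in feature space
seed_centers <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(x, 1, function(p) min(colSums((t(centers) - p)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, x[sample.int(n, 1), , drop = FALSE])
    } else {
      centers <- rbind(centers, x[sample.int(n, 1, prob = d2), , drop = FALSE])
    }
  }
  centers
}

#' Cluster droplet records by volume and velocity
#'
#' Lloyd's k-means on standardized features (z-scored volume and velocity;
#' units are incommensurable, so both axes are given equal weight), with
#' multiple k-means++-seeded restarts keeping the solution with the lowest
#' within-cluster sum of squares. Deterministic for a fixed seed.
#'
#' @param records Droplet records ([make_records()] / [merge_replicates()]).
#' @param k Number of clusters (`1 <= k <= nrow(records)`).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @param transform Feature transform: `"log_volume"` (default) clusters the
#'   logarithm of the volume — droplet volumes span orders of magnitude and
#'   are strongly right-skewed, so the log scale is where Euclidean distances
#'   between them are meaningful — while `"identity"` uses raw volumes.
#' @return A list of class `"spray_clustering"`: `cluster` (assignment),
#'   `centers_std` (standardized-space centroids), `tot_withinss`, `k`,
#'   `seed`, `transform`.
#' @export
cluster_droplets <- function(records, k, seed = 1, restarts = 10,
                             transform = c("log_volume", "identity")) {
  transform <- match.arg(transform)
  n <- nrow(records)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("cannot form ", k, " clusters from ", n, " records")
  x <- cluster_features(records, transform)
  if (k == 1) {
    fit <- list(cluster = rep(1L, n), centers = t(colMeans(x)),
                tot.withinss = sum(scale(x, scale = FALSE)^2))
  } else {
    fit <- with_seed(seed, {
      best <- NULL
      for (r in seq_len(restarts)) {
        f <- tryCatch(
          stats::kmeans(x, centers = seed_centers(x, k),
                        algorithm = "Lloyd", iter.max = 200),
          warning = function(w) suppressWarnings(
            stats::kmeans(x, centers = seed_centers(x, k),
                          algorithm = "Lloyd", iter.max = 500)),
          error = function(e) NULL)
        if (is.null(f)) next
        if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
      }
      if (is.null(best)) stop("k-means failed for every restart")
      best
    })
  }
  structure(list(cluster = as.integer(fit$cluster), centers_std = fit$centers,
                 tot_withinss = fit$tot.withinss, k = as.integer(k),
                 seed = seed, transform = transform),
            class = "spray_clustering")
}

# mean silhouette width of an assignment in feature space
mean_silhouette <- function(x, assignment) {
  sil <- cluster::silhouette(assignment, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Select the number of droplet groups by silhouette
#'
#' Computes the mean silhouette width for each candidate number of clusters
#' (silhouette widths are undefined at k = 1, so candidates start at 2) and
#' returns the k with the largest mean silhouette, ties broken toward
#' smaller k. When even the best candidate has a mean silhouette below 0.5
#' the data show no reliable group structure and a single cluster is
#' reported. This rule makes the conventional visual reading of silhouette
#' plots reproducible.
#'
#' @inheritParams cluster_droplets
#' @param k_range Candidate cluster numbers (default 1:6).
#' @param weak_threshold Mean-silhouette level below which k = 1 is returned.
#' @return A list: `k` (chosen), `mean_silhouette` (named vector over
#'   candidates).
#' @export
select_k <- function(records, k_range = 1:6, seed = 1, restarts = 10,
                     transform = c("log_volume", "identity"),
                     weak_threshold = 0.5) {
  transform <- match.arg(transform)
  n <- nrow(records)
  if (n < 3) stop("cluster-number selection needs at least 3 records")
  ks <- sort(unique(k_range))
  ks <- ks[ks >= 2 & ks <= n - 1]
  if (length(ks) == 0) return(list(k = 1L, mean_silhouette = numeric(0)))
  x <- cluster_features(records, transform)
  sil <- vapply(ks, function(k) {
    fit <- cluster_droplets(records, k, seed = seed, restarts = restarts,
                            transform = transform)
    if (length(unique(fit$cluster)) < 2) return(NA_real_)
    mean_silhouette(x, fit$cluster)
  }, numeric(1))
  names(sil) <- ks
  best <- ks[which.max(sil)]                 # which.max takes the first (smallest) tie
  k <- if (max(sil, na.rm = TRUE) < weak_threshold) 1L else as.integer(best)
  list(k = k, mean_silhouette = sil)
}

#' Group statistics of a clustered spray mode
#'
#' Per cluster: mean and sample standard deviation of droplet volume and
#' velocity, member count, group volume `V_g` (exact sum of member volumes)
#' and fractional volume contribution `V_%`. Groups are reported in order of
#' descending fractional volume, so group 1 is always the dominant carrier
#' of the delivered volume.
#'
#' @param records Droplet records.
#' @param clustering A [cluster_droplets()] result, or an integer assignment
#'   vector.
#' @return An object of class `"spray_mode_result"`: list with `k`, `groups`
#'   (data.frame: `group`, `n`, `volume_mean_nl`, `volume_sd_nl`,
#'   `velocity_mean_ms`, `velocity_sd_ms`, `group_volume_nl`,
#'   `volume_fraction_pct`), `total_volume_nl`, `seed`, and (if available)
#'   `mean_silhouette`.
#' @export
group_stats <- function(records, clustering) {
  assignment <- if (inherits(clustering, "spray_clustering"))
    clustering$cluster else as.integer(clustering)
  if (length(assignment) != nrow(records))
    stop("assignment length does not match the number of records")
  vols <- split(records$volume_nl, assignment)
  vels <- split(records$velocity_ms, assignment)
  g <- data.frame(
    group = seq_along(vols),
    n = lengths(vols),
    volume_mean_nl = vapply(vols, mean, 0),
    volume_sd_nl = vapply(vols, function(x) if (length(x) > 1) stats::sd(x) else 0, 0),
    velocity_mean_ms = vapply(vels, mean, 0),
    velocity_sd_ms = vapply(vels, function(x) if (length(x) > 1) stats::sd(x) else 0, 0),
    group_volume_nl = vapply(vols, sum, 0))
  g$volume_fraction_pct <- volume_fractions(g$group_volume_nl)
  g <- g[order(-g$volume_fraction_pct), ]
  g$group <- seq_len(nrow(g))
  rownames(g) <- NULL
  structure(list(k = nrow(g), groups = g,
                 total_volume_nl = sum(records$volume_nl),
                 seed = if (inherits(clustering, "spray_clustering"))
                   clustering$seed else NA),
            class = "spray_mode_result")
}

#' Fractional volume contributions
#'
#' Percent share of each group volume in the total, `100 * V_g / sum(V_g)`.
#' Invariant to the volume unit.
#'
#' @param group_volumes Group volumes (any common unit).
#' @return Percent fractions summing to 100.
#' @examples
#' volume_fractions(c(1040, 51))       # ~95 / 5
#' volume_fractions(c(611, 107, 724))  # ~42 / 7 / 50
#' @export
volume_fractions <- function(group_volumes) {
  if (any(group_volumes < 0) || sum(group_volumes) <= 0)
    stop("group volumes must be non-negative with a positive total")
  100 * group_volumes / sum(group_volumes)
}

#' @export
print.spray_mode_result <- function(x, digits = 2, ...) {
  cat(sprintf("Spray mode: %d group(s), total evaluated volume %.1f nl\n",
              x$k, x$total_volume_nl))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  group %d (n=%d): <V_d> = %.2f +/- %.2f nl, <v_d> = %.1f +/- %.1f m/s, V_g = %.0f nl (%.0f%%)\n",
                g$group[i], g$n[i], g$volume_mean_nl[i], g$volume_sd_nl[i],
                g$velocity_mean_ms[i], g$velocity_sd_ms[i],
                g$group_volume_nl[i], g$volume_fraction_pct[i]))
  }
  invisible(x)
}
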