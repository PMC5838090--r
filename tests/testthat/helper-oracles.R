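# Independent brute-force oracles, kept deliberately separate from the
# package's own algorithms.

# Exhaustive frame-to-frame assignment: over all maximum-cardinality
# matchings between head positions and next-frame blobs that respect the
# gate and the forward-motion constraint, return the one with minimal total
# Euclidean distance. Recursion over heads (n <= 5).
exhaustive_assignment <- function(heads, blobs, gate_px, geometry) {
  nh <- nrow(heads); nb <- nrow(blobs)
  ax_h <- if (geometry$propagation_axis == "col") heads$col else heads$row
  ax_b <- if (geometry$propagation_axis == "col") blobs$col else blobs$row
  d <- sqrt(outer(heads$row, blobs$row, `-`)^2 + outer(heads$col, blobs$col, `-`)^2)
  feasible <- d <= gate_px &
    geometry$direction * outer(ax_h, ax_b, function(a, b) b - a) >= -1
  best <- list(n = -1L, cost = Inf, assign = rep(NA_integer_, nh))
  recurse <- function(hi, used, assign, cost, nmatch) {
    if (hi > nh) {
      if (nmatch > best$n || (nmatch == best$n && cost < best$cost))
        best <<- list(n = nmatch, cost = cost, assign = assign)
      return(invisible())
    }
    for (bi in seq_len(nb)) {
      if (!used[bi] && feasible[hi, bi]) {
        used[bi] <- TRUE
        assign[hi] <- bi
        recurse(hi + 1L, used, assign, cost + d[hi, bi], nmatch + 1L)
        used[bi] <- FALSE
        assign[hi] <- NA_integer_
      }
    }
    recurse(hi + 1L, used, assign, cost, nmatch)   # leave this head unmatched
  }
  recurse(1L, rep(FALSE, nb), rep(NA_integer_, nh), 0, 0L)
  best$assign
}

# Exhaustive k-means optimum: minimal within-cluster sum of squares over all
# assignments of n points into k non-empty clusters (k^n enumeration,
# vectorized; n <= 12).
exhaustive_kmeans_wcss <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 6e5)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  q <- rowSums(x^2)
  total <- rep(0, nrow(grid))
  nonempty <- rep(TRUE, nrow(grid))
  for (c in seq_len(k)) {
    m <- grid == c
    nc <- rowSums(m)
    nonempty <- nonempty & nc > 0
    sx <- m %*% x[, 1]; sy <- m %*% x[, 2]
    sq <- m %*% q
    contrib <- as.numeric(sq) - (as.numeric(sx)^2 + as.numeric(sy)^2) /
      pmax(nc, 1)
    total <- total + ifelse(nc > 0, contrib, 0)
  }
  min(total[nonempty])
}

# mean silhouette computed from first principles (no cluster:: involved)
naive_mean_silhouette <- function(x, assignment) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment == assignment[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(cl) mean(d[i, assignment == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}
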