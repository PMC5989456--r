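# Independent oracles used across tests. These re-derive expected results by
# brute force and never call the implementation paths they check.

# Exhaustive grid search for the inverse flux-partition problem: for each
# (f, g) on a step-0.01 grid, profile out the scale S in closed form and
# return the grid minimizer of the residual sum of squares.
grid_search_shunt <- function(obs, H, N, step = 0.01) {
  fs <- seq(0, 1, by = step)
  gs <- seq(0, 1, by = step)
  best <- list(rss = Inf)
  for (f in fs) {
    for (g in gs) {
      y <- c(1.5 * H + H * f * g + N, H * (1 - f), H * f, H * f * (1 - g))
      S <- max(0, sum(y * obs) / sum(y * y))
      rss <- sum((obs - S * y)^2)
      if (rss < best$rss - 1e-15) {
        best <- list(f = f, g = g, S = S, rss = rss)
      }
    }
  }
  best
}

# Greedy agglomerative Ward clustering from first principles: at each step
# merge the pair of clusters with the smallest Ward cost
# n_a n_b / (n_a + n_b) * ||centroid_a - centroid_b||^2, ties broken by
# lowest involved sample index. Returns the merge partitions as a list of
# leaf-index sets, one per internal node.
ward_oracle_merges <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        key <- min(c(a, b))
        if (is.null(best) || cost < best$cost - 1e-12 ||
            (abs(cost - best$cost) <= 1e-12 && key < best$key)) {
          best <- list(i = i, j = j, cost = cost, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# Convert an hclust merge matrix into the same representation: the leaf-index
# set formed at each internal node.
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    members <- integer(0)
    for (side in hc$merge[k, ]) {
      members <- c(members,
                   if (side < 0) -side else sets[[side]])
    }
    sets[[k]] <- sort(members)
  }
  sets
}

# Canonical comparison of two merge histories as unordered collections of
# leaf sets (merge order of equal-height merges is irrelevant to topology).
merge_signature <- function(sets) {
  sort(vapply(sets, function(s) paste(s, collapse = "-"), character(1)))
}
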