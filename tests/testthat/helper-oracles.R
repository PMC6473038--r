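# Independent oracles used across the suite. Each recomputes its quantity
# from first principles (raw coordinates, exhaustive enumeration, direct
# sorting) so that agreement with the package is a genuine cross-check.

# Within-cluster sum of squared deviations, straight from member coordinates.
ess_of <- function(pts) {
  if (nrow(pts) <= 1) return(0)
  sum(sweep(pts, 2, colMeans(pts))^2)
}

# Brute-force Ward agglomeration: at every step, evaluate the ESS increase of
# merging every pair of current clusters directly from raw member
# coordinates; merge the cheapest pair, ties to the lexicographically
# smallest (i, j) where a cluster's index is the smallest original row index
# of its members. Returns the merged member sets and costs, step by step.
ward_oracle <- function(pts) {
  clusters <- lapply(seq_len(nrow(pts)), identity)
  steps <- list()
  while (length(clusters) > 1) {
    key <- vapply(clusters, min, numeric(1))
    ord <- order(key)
    clusters <- clusters[ord]
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        merged <- c(clusters[[i]], clusters[[j]])
        cost <- ess_of(pts[merged, , drop = FALSE]) -
          ess_of(pts[clusters[[i]], , drop = FALSE]) -
          ess_of(pts[clusters[[j]], , drop = FALSE])
        if (is.null(best) || cost < best$cost - 1e-12)
          best <- list(i = i, j = j, cost = cost)
      }
    }
    steps[[length(steps) + 1]] <- list(
      members = sort(c(clusters[[best$i]], clusters[[best$j]])),
      cost = best$cost)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  steps
}

# Member sets merged at each step of a ward_linkage result.
ward_merge_members <- function(lk) {
  n <- nrow(lk$points)
  members <- vector("list", nrow(lk$merge))
  leaf <- function(k) if (k < 0) -k else members[[k]]
  for (s in seq_len(nrow(lk$merge)))
    members[[s]] <- sort(c(leaf(lk$merge[s, 1]), leaf(lk$merge[s, 2])))
  members
}

# Exhaustive-outcome binomial upper tail: sum the probability of every
# 0/1 sequence of length n with at least x ones.
binom_tail_enum <- function(x, n, p) {
  if (x == 0) return(1)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  ones <- rowSums(outcomes)
  sum(p^ones[ones >= x] * (1 - p)^(n - ones[ones >= x]))
}

# Direct sort-and-compare Benjamini-Hochberg step-up: returns the logical
# rejection vector at level q.
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(below) > 0) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# Stack-based flood fill over a logical 3-D array, one voxel at a time.
flood_fill_oracle <- function(arr, connectivity = 26) {
  dims <- dim(arr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & rowSums(abs(offs)) <= switch(
    as.character(connectivity), "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, dims)
  cur <- 0L
  for (v in which(arr != 0)) {
    if (lab[v] != 0) next
    cur <- cur + 1L
    stack <- list(arrayInd(v, dims)[1, ])
    lab[v] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > dims)) next
        if (arr[q[1], q[2], q[3]] != 0 && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  lab
}

# Small all-inclusive grid for map tests.
toy_grid <- function(voxel_size = 2, half = 20)
  volume_grid(voxel_size = voxel_size,
              bbox = rbind(c(-half, -half, -half), c(half, half, half)))

# Component membership partitions are equal up to relabelling.
same_partition <- function(a, b) {
  fa <- as.integer(factor(as.vector(a), levels = unique(as.vector(a)[as.vector(a) != 0])))
  stopifnot(length(a) == length(b))
  split_a <- split(seq_along(a), as.vector(a))
  split_b <- split(seq_along(b), as.vector(b))
  setequal(lapply(split_a[names(split_a) != "0"], sort),
           lapply(split_b[names(split_b) != "0"], sort))
}
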