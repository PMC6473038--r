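test_that("two singletons merge at the closed-form Ward cost", {
  lk <- ward_linkage(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(nrow(lk$merge), 1)
  expect_equal(lk$cost, 2)            # 1*1/2 * ||d||^2 = 4/2
  expect_equal(lk$sizes, 2L)
})

test_that("well-separated groups are joined only by the final merge", {
  pts <- rbind(matrix(rnorm(9, sd = 0.5), 3, 3),
               matrix(rnorm(9, sd = 0.5), 3, 3) + 60)
  lk <- ward_linkage(pts)
  last <- ward_merge_members(lk)[[5]]
  expect_equal(last, 1:6)
  # the two triplets are the two clusters one step earlier
  part <- stats::cutree(lk$hclust, k = 2)
  expect_equal(unname(part), rep(1:2, each = 3))
})

test_that("merge sequences equal the brute-force ESS oracle on random sets", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    pts <- matrix(rnorm(3 * n, sd = 10), n, 3)
    lk <- ward_linkage(pts)
    oracle <- ward_oracle(pts)
    expect_equal(ward_merge_members(lk),
                 lapply(oracle, `[[`, "members"))
    expect_equal(lk$cost, vapply(oracle, `[[`, numeric(1), "cost"),
                 tolerance = 1e-9)
  }
})

test_that("Ward costs are monotone and partitions match stats::hclust", {
  set.seed(5)
  pts <- matrix(rnorm(90, sd = 15), 30, 3)
  lk <- ward_linkage(pts)
  expect_false(is.unsorted(lk$cost))
  # independent route: hclust ward.D on squared distances has heights equal
  # to twice the ESS increase and the same nested partitions
  h <- stats::hclust(stats::dist(pts)^2, method = "ward.D")
  expect_equal(lk$cost, h$height / 2, tolerance = 1e-9)
  for (k in c(2, 5, 12)) {
    a <- stats::cutree(lk$hclust, k)
    b <- stats::cutree(h, k)
    expect_true(same_partition(a, b))
  }
})

test_that("total sum of squares is conserved across any cut", {
  set.seed(9)
  pts <- matrix(rnorm(60, sd = 8), 20, 3)
  lk <- ward_linkage(pts)
  tss <- ess_of(pts)
  for (k in c(1, 3, 7, 20)) {
    part <- stats::cutree(lk$hclust, k)
    within <- sum(vapply(split(seq_len(20), part), function(ix)
      ess_of(pts[ix, , drop = FALSE]), numeric(1)))
    grand <- colMeans(pts)
    between <- sum(vapply(split(seq_len(20), part), function(ix) {
      m <- colMeans(pts[ix, , drop = FALSE])
      length(ix) * sum((m - grand)^2)
    }, numeric(1)))
    expect_equal(within + between, tss, tolerance = 1e-9 * tss)
  }
})

test_that("identical points collapse to one zero-spread cluster", {
  pts <- matrix(rep(c(3, -4, 5), each = 12), 12, 3)
  sol <- cut_at_resolution(ward_linkage(pts), 5)
  expect_equal(sol$k, 1)
  expect_equal(unlist(sol$summaries[, c("sd_x", "sd_y", "sd_z")],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("two planted 3-mm blobs 40 mm apart are recovered as two clusters", {
  set.seed(21)
  centers <- rbind(c(-20, 0, 0), c(20, 0, 0))
  pts <- rbind(matrix(rnorm(60, sd = 3), 20, 3) +
                 rep(centers[1, ], each = 20),
               matrix(rnorm(60, sd = 3), 20, 3) +
                 rep(centers[2, ], each = 20))
  sol <- cut_at_resolution(ward_linkage(pts), 5)
  expect_equal(sol$k, 2)
  got <- as.matrix(sol$summaries[order(sol$summaries$x), c("x", "y", "z")])
  expect_lt(max(abs(got - centers)), 2)
})

test_that("a 12-mm blob cannot satisfy the 5-mm criterion as one cluster", {
  set.seed(33)
  pts <- matrix(rnorm(90, sd = 12), 30, 3)
  sol <- cut_at_resolution(ward_linkage(pts), 5)
  expect_gt(sol$k, 1)
})

test_that("the cut is nested: coarser resolutions never give more clusters", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(45, sd = 4), 15, 3),
               matrix(rnorm(45, sd = 6), 15, 3) + 30,
               matrix(runif(30, -50, 50), 10, 3))
  lk <- ward_linkage(pts)
  ks <- vapply(c(2, 4, 6, 8, 12), function(res)
    cut_at_resolution(lk, res)$k, numeric(1))
  expect_false(is.unsorted(rev(ks)))
})

test_that("the per-cluster-maximum criterion is at least as strict", {
  set.seed(17)
  pts <- rbind(matrix(rnorm(45, sd = 4.5), 15, 3),
               matrix(runif(45, -60, 60), 15, 3))
  lk <- ward_linkage(pts)
  k_mean <- cut_at_resolution(lk, 5, criterion = "mean")$k
  k_max <- cut_at_resolution(lk, 5, criterion = "max")$k
  expect_gte(k_max, k_mean)
  sol_max <- cut_at_resolution(lk, 5, criterion = "max")
  expect_true(all(as.matrix(
    sol_max$summaries[, c("sd_x", "sd_y", "sd_z")]) <= 5))
})

test_that("label summaries count every focus exactly once", {
  pts <- rbind(matrix(rnorm(15, sd = 1), 5, 3),
               matrix(rnorm(9, sd = 1), 3, 3) + 50)
  sol <- cut_at_resolution(ward_linkage(pts), 5,
                           labels = c("a", "a", "a", "b", "b",
                                      "b", "b", "b"))
  expect_equal(sol$k, 2)
  s <- sol$summaries
  expect_equal(s$n_a + s$n_b, s$size)
  expect_equal(sum(s$size), 8)
  one <- s[s$size == 5, ]
  expect_equal(c(one$n_a, one$n_b), c(3L, 2L))
  expect_error(summarize_clusters(sol, c("a", "b")), "does not match")
})

test_that("singletons report zero spread and a single label", {
  sol <- cut_at_resolution(ward_linkage(rbind(c(0, 0, 0), c(60, 0, 0))), 5,
                           labels = c("a", "b"))
  expect_equal(sol$k, 2)
  expect_true(all(sol$summaries[, c("sd_x", "sd_y", "sd_z")] == 0))
  expect_true(all(rowSums(sol$summaries[, c("n_a", "n_b")]) == 1))
})

test_that("degenerate inputs raise dataset errors", {
  expect_error(ward_linkage(matrix(numeric(0), 0, 3)), "at least one point")
  lk <- ward_linkage(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(cut_at_resolution(lk, 0), "positive")
  expect_error(cut_at_resolution(lk, -3), "positive")
})
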