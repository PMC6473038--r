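kernel_peak <- function(fwhm, vs) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  (2 * pi * sigma^2)^(-1.5) * vs^3
}

test_that("a single focus yields the kernel's central value at its voxel", {
  grid <- toy_grid()
  ma <- ma_map(rbind(c(0, 0, 0)), grid, fwhm_mm = 10)
  expect_equal(max(ma$values), kernel_peak(10, 2))
  ctr <- round(mm_to_vox(grid, matrix(0, 1, 3)))[1, ]
  expect_equal(ma$values[ctr[1], ctr[2], ctr[3]], kernel_peak(10, 2))
})

test_that("coincident and duplicated foci do not inflate the MA map", {
  grid <- toy_grid()
  one <- ma_map(rbind(c(4, -6, 2)), grid, 10)
  two <- ma_map(rbind(c(4, -6, 2), c(4, -6, 2)), grid, 10)
  expect_equal(two$values, one$values)
})

test_that("between two foci 2*FWHM apart, the midpoint sees kernel(FWHM)", {
  grid <- toy_grid(voxel_size = 2)
  fwhm <- 8   # foci at x = -8 and +8, midpoint x = 0, all on voxel centres
  ma <- ma_map(rbind(c(-fwhm, 0, 0), c(fwhm, 0, 0)), grid, fwhm)
  mid <- round(mm_to_vox(grid, matrix(0, 1, 3)))[1, ]
  # at distance FWHM the Gaussian has fallen to 2^-4 of its peak
  expect_equal(ma$values[mid[1], mid[2], mid[3]],
               kernel_peak(fwhm, 2) / 16, tolerance = 1e-9)
})

test_that("out-of-grid foci warn and clip", {
  grid <- toy_grid(half = 10)
  expect_warning(ma <- ma_map(rbind(c(200, 0, 0)), grid, 10), "outside")
  expect_true(all(ma$values == 0))
})

test_that("ALE union follows 1 - prod(1 - MA) and its algebra", {
  grid <- toy_grid(half = 8)
  m1 <- ma_map(rbind(c(0, 0, 0)), grid, 12)
  m2 <- ma_map(rbind(c(6, 0, 0)), grid, 12)
  # one experiment: identity
  expect_equal(ale_union(list(m1))$values, m1$values)
  # direct formula, including the 0.5/0.5 -> 0.75 arithmetic
  ale <- ale_union(list(m1, m2))
  expect_equal(ale$values, 1 - (1 - m1$values) * (1 - m2$values),
               tolerance = 1e-12)
  half <- stat_map(grid, array(0.5, grid$dim), "MA")
  expect_equal(unique(as.vector(ale_union(list(half, half))$values)), 0.75)
  # bounds and invariances
  expect_true(all(ale$values >= pmax(m1$values, m2$values) - 1e-15))
  expect_true(all(ale$values >= 0 & ale$values < 1))
  expect_equal(ale_union(list(m2, m1))$values, ale$values)
  zero <- stat_map(grid, array(0, grid$dim), "MA")
  expect_equal(ale_union(list(m1, m2, zero))$values, ale$values)
})

test_that("moving a duplicate focus to its own experiment never lowers ALE", {
  grid <- toy_grid(half = 8)
  within <- ale_union(list(ma_map(rbind(c(0, 0, 0), c(0, 0, 0)), grid, 10)))
  across <- ale_union(list(ma_map(rbind(c(0, 0, 0)), grid, 10),
                           ma_map(rbind(c(0, 0, 0)), grid, 10)))
  expect_true(all(across$values >= within$values - 1e-15))
})

test_that("the Monte-Carlo null is reproducible, bounded and discriminates", {
  grid <- toy_grid(voxel_size = 4, half = 20)
  null1 <- mc_null(c(1), grid, 10, n_iter = 100, seed = 7)
  null2 <- mc_null(c(1), grid, 10, n_iter = 100, seed = 7)
  expect_identical(null1$counts, null2$counts)
  # single-experiment, single-focus null never exceeds the kernel peak
  expect_lte(null1$upper_max, kernel_peak(10, 4))
  # a planted hotspot is more surprising than background
  foci <- lapply(1:6, function(i) rbind(c(0, 0, 0) + rnorm(3, sd = 2)))
  ale <- ale_union(lapply(foci, ma_map, grid = grid, fwhm_mm = 10))
  null <- mc_null(rep(1, 6), grid, 10, n_iter = 150, seed = 11)
  hot <- max(ale$values)
  bg_vox <- round(mm_to_vox(grid, matrix(c(-16, -16, -16), 1)))[1, ]
  bg <- ale$values[bg_vox[1], bg_vox[2], bg_vox[3]]
  p <- null_pvalue(null, c(hot, bg))
  expect_lt(p[1], p[2])
  # stability: doubling the iterations moves the 95th percentile < 5%
  q95 <- function(nl) {
    cum <- cumsum(nl$counts) / nl$n_total
    nl$breaks[-1][which(cum >= 0.95)[1]]
  }
  null_b <- mc_null(rep(1, 6), grid, 10, n_iter = 300, seed = 12)
  expect_lt(abs(q95(null_b) - q95(null)) / q95(null), 0.05)
})

test_that("FDR thresholding matches a direct BH oracle and is sane", {
  # all-zero p survives everywhere; the BH cut matches sort-and-compare
  grid <- toy_grid(voxel_size = 4, half = 10)
  set.seed(31)
  p <- runif(1000)
  q <- 0.1
  reject_pkg <- stats::p.adjust(p, "BH") <= q
  expect_identical(reject_pkg, bh_oracle(p, q))
  # through the map interface: a null with mass at zero gives p ~ 1 for
  # zero voxels and everything survives when every p is (numerically) zero
  null <- mc_null(c(2), grid, 10, n_iter = 100, seed = 3)
  ale0 <- stat_map(grid, array(0, grid$dim), "ALE")
  res0 <- threshold_fdr(ale0, null, q = 0.05)
  expect_equal(sum(res0$binary$values), 0)  # all p = 1 -> empty, no error
  hotv <- null$breaks[length(null$breaks)] * 2
  ale1 <- stat_map(grid, array(hotv, grid$dim), "ALE")
  res1 <- threshold_fdr(ale1, null, q = 0.05)
  expect_equal(mean(res1$binary$values), 1)  # all p = 0 -> all survive
})

test_that("under a pure null, the surviving voxel fraction respects q", {
  grid <- toy_grid(voxel_size = 4, half = 16)
  null <- mc_null(c(3, 3), grid, 12, n_iter = 200, seed = 21)
  # observed maps drawn from the same process as the null
  set.seed(22)
  fp <- replicate(10, {
    foci <- lapply(1:2, function(i)
      matrix(runif(9, -16, 16), 3, 3))
    ale <- ale_union(lapply(foci, ma_map, grid = grid, fwhm_mm = 12))
    mean(threshold_fdr(ale, null, q = 0.05)$binary$values)
  })
  expect_lte(mean(fp), 0.05)
})

test_that("extent thresholding keeps 304 mm^3 and drops 296 mm^3 at 2 mm", {
  grid <- toy_grid(voxel_size = 2, half = 12)
  arr <- array(0, grid$dim)
  arr[2:38] <- 1                      # 37 voxels * 8 = 296 mm^3, one line
  b37 <- stat_map(grid, arr, "binary")
  expect_equal(sum(extent_threshold(b37, 300)$values), 0)
  arr[39] <- 1                        # 38 voxels = 304 mm^3
  b38 <- stat_map(grid, arr, "binary")
  expect_equal(sum(extent_threshold(b38, 300)$values), 38)
})

test_that("components and extent filtering match the flood-fill oracle", {
  set.seed(14)
  grid <- toy_grid(voxel_size = 2, half = 8)
  arr <- array(rbinom(prod(grid$dim), 1, 0.2), grid$dim)
  lab <- label_components(arr, 26)
  oracle <- flood_fill_oracle(arr, 26)
  expect_true(same_partition(lab, oracle))
  # extent threshold = oracle components filtered by volume
  keep_oracle <- array(0, dim(arr))
  sizes <- tabulate(oracle[oracle > 0])
  keep_oracle[oracle %in% which(sizes * 8 > 40)] <- 1
  got <- extent_threshold(stat_map(grid, arr, "binary"), 40)
  expect_equal(got$values, keep_oracle)
  # monotone: raising the threshold never adds voxels
  more <- extent_threshold(stat_map(grid, arr, "binary"), 80)
  expect_true(all(more$values <= got$values))
})

test_that("conjunction is a commutative, associative, idempotent minimum", {
  grid <- toy_grid(voxel_size = 2, half = 2)
  set.seed(6)
  a <- stat_map(grid, array(runif(prod(grid$dim)), grid$dim), "ALE")
  b <- stat_map(grid, array(runif(prod(grid$dim)), grid$dim), "ALE")
  c_ <- stat_map(grid, array(runif(prod(grid$dim)), grid$dim), "ALE")
  expect_equal(conjunction(a, a)$values, a$values)
  expect_equal(conjunction(a, b)$values, conjunction(b, a)$values)
  expect_equal(conjunction(conjunction(a, b), c_)$values,
               conjunction(a, conjunction(b, c_))$values)
  zero <- stat_map(grid, array(0, grid$dim), "ALE")
  expect_true(all(conjunction(a, zero)$values == 0))
  # hand-enumerated 2x2x2 minima
  g2 <- volume_grid(voxel_size = 1, bbox = rbind(c(0, 0, 0), c(1, 1, 1)))
  va <- array(c(1, 2, 3, 4, 5, 6, 7, 8) / 10, c(2, 2, 2))
  vb <- array(c(8, 7, 6, 5, 4, 3, 2, 1) / 10, c(2, 2, 2))
  expect_equal(conjunction(stat_map(g2, va, "ALE"),
                           stat_map(g2, vb, "ALE"))$values,
               array(c(1, 2, 3, 4, 4, 3, 2, 1) / 10, c(2, 2, 2)))
  # suprathreshold sets intersect at any common threshold
  thr <- 0.4
  expect_equal(conjunction(a, b)$values > thr,
               (a$values > thr) & (b$values > thr))
})

test_that("cluster reports locate volumes, centres and extrema", {
  grid <- toy_grid(voxel_size = 2, half = 10)
  arr <- array(0, grid$dim)
  ctr <- round(mm_to_vox(grid, matrix(c(4, -2, 6), 1)))[1, ]
  arr[ctr[1], ctr[2], ctr[3]] <- 1
  bin <- stat_map(grid, arr, "binary")
  ale <- stat_map(grid, arr * 0.5, "ALE")
  rep1 <- ale_cluster_report(bin, ale)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$volume_mm3, 8)
  expect_equal(c(rep1$wc_x, rep1$wc_y, rep1$wc_z), c(4, -2, 6))
  expect_equal(rep1$peak_ale, 0.5)
  # symmetric two-voxel cluster: weighted centre at the midpoint
  arr[ctr[1] + 1, ctr[2], ctr[3]] <- 1
  ale2 <- stat_map(grid, arr * 0.3, "ALE")
  rep2 <- ale_cluster_report(stat_map(grid, arr, "binary"), ale2)
  expect_equal(rep2$wc_x, 5)
  # a planted Gaussian hotspot reports a centre within one voxel
  focus <- c(-6, 4, -2)
  ma <- ma_map(rbind(focus), grid, 10)
  thr <- stat_map(grid, (ma$values > 0.4 * max(ma$values)) + 0, "binary")
  rep3 <- ale_cluster_report(thr, ma)
  expect_lt(sqrt(sum((c(rep3$wc_x, rep3$wc_y, rep3$wc_z) - focus)^2)), 2)
  expect_equal(c(rep3$peak_x, rep3$peak_y, rep3$peak_z), focus)
  # empty map -> empty table
  expect_equal(nrow(ale_cluster_report(stat_map(grid, array(0, grid$dim),
                                                "binary"), ma)), 0)
})

test_that("cluster validation by map intersection honours the radius", {
  set.seed(44)
  grid <- toy_grid(voxel_size = 2, half = 16)
  pts <- rbind(matrix(rnorm(30, sd = 1), 10, 3),           # at origin
               matrix(rnorm(30, sd = 1), 10, 3) +
                 rep(c(0, -14, 0), each = 10),             # near a blob
               matrix(rnorm(30, sd = 1), 10, 3) +
                 rep(c(14, 14, 14), each = 10))            # far away
  sol <- cut_at_resolution(ward_linkage(pts), 5)
  arr <- array(0, grid$dim)
  hot <- round(mm_to_vox(grid, matrix(c(0, -2, 0), 1)))[1, ]
  arr[hot[1], hot[2], hot[3]] <- 1
  val <- intersect_with_clusters(sol, stat_map(grid, arr, "binary"),
                                 radius_mm = 5)
  near_origin <- which.min(rowSums(val[, c("x", "y", "z")]^2))
  expect_true(val$validated[near_origin])
  expect_equal(sum(val$validated), 1)
  # empty surviving map validates nothing
  val0 <- intersect_with_clusters(sol, stat_map(grid, array(0, grid$dim),
                                                "binary"))
  expect_false(any(val0$validated))
})

test_that("NIfTI round trips preserve values and geometry", {
  grid <- toy_grid(voxel_size = 2, half = 6)
  ma <- ma_map(rbind(c(0, 2, -4)), grid, 10)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_stat_map(ma, path)
  back <- read_stat_map(path, kind = "MA")
  expect_equal(back$values, ma$values, tolerance = 1e-6)
  expect_equal(back$grid$affine, grid$affine, tolerance = 1e-6)
})
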