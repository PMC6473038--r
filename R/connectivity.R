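#' Construct a preprocessed BOLD run
#'
#' A \code{bold_run} holds one subject's already-preprocessed resting-state
#' series on a grid: a voxels x time matrix in grid array order. Runs entering
#' a group analysis must share one grid.
#'
#' @param grid a \code{\link{volume_grid}}.
#' @param series numeric matrix, \code{prod(grid$dim)} rows (voxels, array
#'   order) by T columns (time points, T >= 20).
#' @param subject_id identifier.
#' @return An object of class \code{bold_run}.
#' @export
bold_run <- function(grid, series, subject_id = "s1") {
  stopifnot(inherits(grid, "volume_grid"))
  series <- as.matrix(series)
  if (nrow(series) != prod(grid$dim))
    stop("series must have one row per grid voxel")
  if (ncol(series) < 20) stop("BOLD runs need at least 20 time points")
  if (any(!is.finite(series))) stop("non-finite values in BOLD series")
  structure(list(grid = grid, series = series, subject_id = subject_id,
                 T = ncol(series)),
            class = "bold_run")
}

#' Spherical seed region of interest
#'
#' @param center 3-vector, MNI mm.
#' @param radius_mm sphere radius; default 5 (the clustering resolution, so a
#'   seed built on a cluster centroid covers the cluster's spatial grain).
#' @return An object of class \code{seed_roi}.
#' @export
seed_roi <- function(center, radius_mm = 5) {
  stopifnot(length(center) == 3, is.finite(radius_mm), radius_mm > 0)
  structure(list(center = as.numeric(center), radius_mm = radius_mm),
            class = "seed_roi")
}

#' Voxel indices covered by a seed on a grid
#'
#' @param roi a \code{\link{seed_roi}} or an explicit integer vector of
#'   linear voxel indices (returned as-is).
#' @param grid a \code{\link{volume_grid}}.
#' @return Integer vector of linear voxel indices inside the sphere and the
#'   grid mask.
#' @export
roi_voxels <- function(roi, grid) {
  if (is.numeric(roi) && is.null(attr(roi, "class"))) return(as.integer(roi))
  stopifnot(inherits(roi, "seed_roi"))
  half <- ceiling(roi$radius_mm / grid$voxel_size) + 1L
  ctr <- round(mm_to_vox(grid, matrix(roi$center, 1)))[1, ]
  lo <- pmax(1, ctr - half); hi <- pmin(grid$dim, ctr + half)
  if (any(lo > hi)) stop("seed sphere lies outside the grid")
  box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  mm <- vox_to_mm(grid, box)
  d2 <- colSums((t(mm) - roi$center)^2)
  box <- box[d2 <= roi$radius_mm^2, , drop = FALSE]
  idx <- box[, 1] + (box[, 2] - 1L) * grid$dim[1] +
    (box[, 3] - 1L) * grid$dim[1] * grid$dim[2]
  idx <- idx[grid$mask[idx]]
  if (length(idx) == 0) stop("seed region does not intersect the grid mask")
  as.integer(idx)
}

#' Mean seed time course
#'
#' Unweighted mean of the run's series over the seed voxels at each time
#' point.
#'
#' @param run a \code{\link{bold_run}}.
#' @param roi a \code{\link{seed_roi}} or voxel index vector.
#' @return Numeric vector of length T.
#' @export
seed_series <- function(run, roi) {
  idx <- roi_voxels(roi, run$grid)
  colMeans(run$series[idx, , drop = FALSE])
}

#' Seed-to-voxel Pearson correlation map
#'
#' Pearson correlation between the seed time course and every voxel's time
#' course. Voxels with zero variance are assigned r = 0.
#'
#' @param run a \code{\link{bold_run}}.
#' @param seed numeric seed time course of length T.
#' @return A \code{\link{stat_map}} of kind \code{"r"}.
#' @export
correlation_map <- function(run, seed) {
  if (length(seed) != run$T) stop("seed series length does not match run")
  if (stats::sd(seed) == 0) stop("seed series has zero variance")
  sc <- seed - mean(seed)
  sc <- sc / sqrt(sum(sc^2))
  x <- run$series - rowMeans(run$series)
  norms <- sqrt(rowSums(x^2))
  r <- as.numeric(x %*% sc) / norms
  r[norms == 0] <- 0
  r <- pmin(1, pmax(-1, r))
  stat_map(run$grid, array(r, run$grid$dim), kind = "r")
}

#' Fisher z-transform of a correlation map
#'
#' \eqn{z = \mathrm{atanh}(r)}, clipped to \code{|z| <= z_max} so that voxels
#' with r = +/-1 stay finite.
#'
#' @param rmap a \code{\link{stat_map}} of kind \code{"r"} (or a numeric
#'   vector/array of correlations).
#' @param z_max clipping bound; default 18.
#' @return A \code{stat_map} of kind \code{"z"} (or numeric like the input).
#' @export
fisher_z <- function(rmap, z_max = 18) {
  f <- function(r) pmin(z_max, pmax(-z_max, atanh(pmin(1, pmax(-1, r)))))
  if (inherits(rmap, "stat_map"))
    stat_map(rmap$grid, array(f(rmap$values), rmap$grid$dim), kind = "z")
  else f(rmap)
}

## voxels x subjects matrix from a list of z stat_maps (or a matrix)
.map_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  grid <- maps[[1]]$grid
  for (m in maps[-1]) .check_same_grid(maps[[1]], m)
  out <- vapply(maps, function(m) as.numeric(m$values), numeric(prod(grid$dim)))
  attr(out, "grid") <- grid
  out
}

## one-sided voxel-wise t statistics for columns-as-subjects difference maps
.voxel_t <- function(D) {
  nsub <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(pmax(0, rowSums((D - m)^2) / (nsub - 1)))
  t <- m / (s / sqrt(nsub))
  t[s == 0 & m == 0] <- 0
  t[s == 0 & m > 0] <- Inf
  t[s == 0 & m < 0] <- -Inf
  t
}

## size of the largest suprathreshold cluster (t > tcrit), 26-connectivity
.max_cluster_size <- function(t, tcrit, grid, connectivity = 26) {
  supra <- array(t > tcrit & grid$mask, grid$dim)
  if (!any(supra)) return(0L)
  lab <- label_components(supra, connectivity)
  max(tabulate(lab[lab > 0]))
}

#' Paired group contrast with permutation cluster-FWE correction
#'
#' Voxel-wise paired t-test of condition A against condition B across
#' subjects: the one-sided t statistic of the per-subject difference maps
#' (A - B > 0). Clusters are formed among voxels whose uncorrected one-sided
#' p falls below \code{voxel_p}, and a cluster survives when its size exceeds
#' the \eqn{100(1 - \alpha)} percentile of the maximum-cluster-size null
#' obtained by randomly sign-flipping whole-subject difference maps
#' (\code{n_perm} iterations, seed-controlled) — an exact exchangeability
#' argument for the paired design.
#'
#' @param zmaps_a,zmaps_b per-subject z maps (lists of \code{stat_map}s, or
#'   voxels x subjects matrices), same subjects in the same order; for a
#'   one-sample (simple-effect) test pass \code{zmaps_b = NULL}.
#' @param grid the shared \code{\link{volume_grid}} (required when matrices
#'   are passed).
#' @param voxel_p cluster-forming uncorrected one-sided level; default 0.001.
#' @param cluster_fwe family-wise cluster level; default 0.05.
#' @param n_perm sign-flip iterations; default 1000.
#' @param seed integer seed.
#' @param connectivity cluster connectivity; default 26.
#' @return A \code{group_result}: list with \code{t} and \code{p}
#'   \code{stat_map}s, \code{corrected} (binary map of surviving clusters),
#'   \code{clusters} (per-cluster size/peak table), \code{crit_size} (null
#'   percentile of max cluster size), \code{null_max_sizes}, \code{df},
#'   \code{n_subjects}.
#' @export
paired_contrast <- function(zmaps_a, zmaps_b = NULL, grid = NULL,
                            voxel_p = 0.001, cluster_fwe = 0.05,
                            n_perm = 1000, seed = 1L, connectivity = 26) {
  A <- .map_matrix(zmaps_a)
  if (is.null(grid)) grid <- attr(A, "grid")
  if (is.null(grid)) stop("grid must be supplied when passing matrices")
  if (!is.null(zmaps_b)) {
    B <- .map_matrix(zmaps_b)
    if (!all(dim(A) == dim(B)))
      stop("condition maps disagree in voxels or subjects")
    D <- A - B
  } else {
    D <- A
  }
  nsub <- ncol(D)
  if (nsub < 6) stop("need at least 6 subjects")
  df <- nsub - 1
  tcrit <- stats::qt(voxel_p, df, lower.tail = FALSE)
  tobs <- .voxel_t(D)
  pobs <- stats::pt(tobs, df, lower.tail = FALSE)
  supra <- array(tobs > tcrit & grid$mask, grid$dim)
  lab <- label_components(supra, connectivity)
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    signs <- sample(c(-1, 1), nsub, replace = TRUE)
    tp <- .voxel_t(sweep(D, 2, signs, `*`))
    .max_cluster_size(tp, tcrit, grid, connectivity)
  }, numeric(1))
  crit_size <- stats::quantile(null_max, 1 - cluster_fwe, type = 1,
                               names = FALSE)
  corrected <- array(0, grid$dim)
  clusters <- data.frame(cluster = integer(0), n_voxels = integer(0),
                         volume_mm3 = numeric(0), max_t = numeric(0),
                         p_fwe = numeric(0), survives = logical(0))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes > crit_size)
    corrected[lab %in% keep] <- 1
    clusters <- do.call(rbind, lapply(order(-sizes), function(cl) {
      idx <- which(lab == cl)
      data.frame(cluster = cl, n_voxels = sizes[cl],
                 volume_mm3 = sizes[cl] * grid$voxel_size^3,
                 max_t = max(tobs[idx]),
                 p_fwe = mean(null_max >= sizes[cl]),
                 survives = sizes[cl] > crit_size)
    }))
    rownames(clusters) <- NULL
  }
  parr <- array(1, grid$dim); parr[grid$mask] <- pobs[as.vector(grid$mask)]
  structure(list(t = stat_map(grid, array(tobs, grid$dim), kind = "t"),
                 p = stat_map(grid, parr, kind = "p"),
                 corrected = stat_map(grid, corrected, kind = "binary"),
                 clusters = clusters, crit_size = crit_size,
                 null_max_sizes = null_max, df = df, n_subjects = nsub,
                 voxel_p = voxel_p, cluster_fwe = cluster_fwe, seed = seed),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(paste0("group_result: paired/one-sample t, %d subjects, ",
                     "%d cluster(s), %d surviving (crit size > %g voxels)\n"),
              x$n_subjects, nrow(x$clusters), sum(x$clusters$survives),
              x$crit_size))
  invisible(x)
}

#' Conjunction of two simple effects
#'
#' Voxel-wise minimum of the two one-sample (simple-effect) t maps, masked to
#' the voxels that survive BOTH corrected maps: non-zero exactly where each
#' seed's connectivity is individually significant, with the conservative
#' minimum statistic as the map value.
#'
#' @param group_a,group_b \code{group_result}s of the two simple effects.
#' @return A \code{\link{stat_map}} of kind \code{"t"}.
#' @export
conjunction_simple_effects <- function(group_a, group_b) {
  .check_same_grid(group_a$t, group_b$t)
  both <- group_a$corrected$values * group_b$corrected$values
  stat_map(group_a$t$grid,
           pmin(group_a$t$values, group_b$t$values) * both, kind = "t")
}
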