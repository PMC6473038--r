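#' Modelled-activation (MA) map for one experiment
#'
#' Builds the per-experiment modelled-activation map used by activation
#' likelihood estimation. Each focus contributes an isotropic 3-D Gaussian
#' kernel, scaled as a proper probability density integrated over the voxel
#' (voxel value = density x voxel volume, so values live in [0, 1)). Within
#' an experiment the kernels combine NON-additively: the voxel value is the
#' maximum over the experiment's foci, so multiple nearby peaks from one
#' experiment cannot inflate the map beyond a single kernel's height.
#'
#' @param experiment_foci n x 3 matrix of focus coordinates (MNI mm).
#' @param grid a \code{\link{volume_grid}}.
#' @param fwhm_mm kernel full width at half maximum, mm; default 10.
#' @param truncate kernel support radius in standard deviations; default 4.
#' @return A \code{\link{stat_map}} of kind \code{"MA"}.
#' @export
ma_map <- function(experiment_foci, grid, fwhm_mm = 10, truncate = 4) {
  foci <- .as_point_matrix(experiment_foci)
  if (nrow(foci) < 1) stop("ma_map needs at least one focus")
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- grid$voxel_size
  peak_scale <- (2 * pi * sigma^2)^(-1.5) * vs^3
  half <- ceiling(truncate * sigma / vs)
  arr <- array(0, grid$dim)
  for (i in seq_len(nrow(foci))) {
    fv <- mm_to_vox(grid, foci[i, , drop = FALSE])[1, ]
    ctr <- round(fv)
    if (any(ctr < 1 - half) || any(ctr > grid$dim + half)) {
      warning("focus ", paste(round(foci[i, ], 1), collapse = ","),
              " lies outside the grid; contribution clipped")
    }
    lo <- pmax(1, ctr - half); hi <- pmin(grid$dim, ctr + half)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    ## squared mm distance from the focus to each voxel centre in the box
    dx2 <- ((ix - fv[1]) * vs)^2
    dy2 <- ((iy - fv[2]) * vs)^2
    dz2 <- ((iz - fv[3]) * vs)^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    k <- peak_scale * exp(-d2 / (2 * sigma^2))
    arr[ix, iy, iz] <- pmax(arr[ix, iy, iz], k)
  }
  arr <- pmin(arr, 1 - 1e-12)
  stat_map(grid, arr, kind = "MA")
}

#' ALE union of modelled-activation maps
#'
#' Combines per-experiment MA maps into the ALE map by the probabilistic
#' union \eqn{ALE = 1 - \prod_i (1 - MA_i)} at each voxel: the probability
#' that at least one experiment activates there, treating experiments as
#' independent.
#'
#' @param ma_maps list of \code{\link{stat_map}}s of kind \code{"MA"} on a
#'   shared grid.
#' @return A \code{\link{stat_map}} of kind \code{"ALE"}.
#' @export
ale_union <- function(ma_maps) {
  stopifnot(length(ma_maps) >= 1)
  for (m in ma_maps[-1]) .check_same_grid(ma_maps[[1]], m)
  log_surv <- array(0, ma_maps[[1]]$grid$dim)
  for (m in ma_maps) log_surv <- log_surv + log1p(-m$values)
  stat_map(ma_maps[[1]]$grid, 1 - exp(log_surv), kind = "ALE")
}

#' Monte-Carlo spatial-randomisation null for ALE
#'
#' Builds an empirical null distribution of voxel-wise ALE values under the
#' hypothesis of no spatial convergence: at every iteration each experiment's
#' foci are relocated uniformly at random within the grid mask (uniform over
#' mask voxels, jittered uniformly within the voxel), the ALE map is
#' recomputed, and all in-mask voxel values are pooled into a fixed-bin
#' histogram. P-values are the empirical upper-tail fractions, evaluated
#' conservatively at the bin containing the observed value.
#'
#' @param foci_design integer vector: number of foci of each experiment.
#' @param grid a \code{\link{volume_grid}}.
#' @param fwhm_mm kernel FWHM, mm.
#' @param n_iter number of randomisation iterations (>= 100).
#' @param seed integer seed; the null is reproducible given the seed.
#' @param n_bins histogram resolution; default 4096.
#' @return An object of class \code{ale_null}: list with \code{breaks},
#'   \code{counts}, \code{n_total}, \code{upper_max} (largest simulated
#'   value), \code{n_iter}, \code{seed}, \code{foci_design}.
#' @export
mc_null <- function(foci_design, grid, fwhm_mm = 10, n_iter = 200,
                    seed = 1L, n_bins = 4096) {
  foci_design <- as.integer(foci_design)
  stopifnot(all(foci_design >= 1))
  if (n_iter < 100) stop("n_iter must be at least 100")
  mask_idx <- which(grid$mask)
  if (length(mask_idx) == 0) stop("grid mask is empty")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kmax <- (2 * pi * sigma^2)^(-1.5) * grid$voxel_size^3
  vmax <- 1 - (1 - kmax)^length(foci_design)
  breaks <- seq(0, vmax * (1 + 1e-9), length.out = n_bins + 1)
  counts <- numeric(n_bins)
  vs <- grid$voxel_size
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  observed_max <- 0
  for (it in seq_len(n_iter)) {
    mas <- lapply(foci_design, function(nf) {
      vox <- arrayInd(sample(mask_idx, nf, replace = TRUE), grid$dim)
      jit <- matrix(stats::runif(3 * nf, -0.5, 0.5), ncol = 3)
      ma_map(vox_to_mm(grid, vox) + jit * vs, grid, fwhm_mm)
    })
    ale <- ale_union(mas)$values[mask_idx]
    observed_max <- max(observed_max, ale)
    ## value in (breaks[b], breaks[b+1]] -> bin b; exact zeros fall in bin 1
    bins <- findInterval(ale, breaks, left.open = TRUE,
                         rightmost.closed = TRUE)
    bins <- pmax(1L, pmin(n_bins, bins))
    counts <- counts + tabulate(bins, nbins = n_bins)
  }
  structure(list(breaks = breaks, counts = counts,
                 n_total = sum(counts), upper_max = observed_max,
                 n_iter = n_iter, seed = seed, foci_design = foci_design),
            class = "ale_null")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Empirical upper-tail p-values from an ALE null
#'
#' @param null an \code{ale_null} from \code{\link{mc_null}}.
#' @param values numeric vector of observed ALE values.
#' @return P-values \eqn{P(\mathrm{null} \ge v)}, conservative at histogram
#'   resolution (all mass in the observed value's bin counts as at-or-above).
#' @export
null_pvalue <- function(null, values) {
  stopifnot(inherits(null, "ale_null"))
  upper_from <- rev(cumsum(rev(null$counts))) # mass in bins >= b
  b <- findInterval(values, null$breaks, left.open = TRUE,
                    rightmost.closed = TRUE)
  b <- pmax(1L, pmin(length(null$counts), b))
  p <- upper_from[b] / null$n_total
  p[values > null$breaks[length(null$breaks)]] <- 0
  pmin(1, pmax(p, 0))
}

#' Voxel-wise FDR thresholding (pID)
#'
#' Converts an ALE map to empirical p-values against a Monte-Carlo null and
#' applies the Benjamini-Hochberg step-up procedure, valid under positive
#' dependence (the "pID" variant), at level \code{q}. Voxels whose adjusted
#' p-value is at or below \code{q} survive.
#'
#' @param ale a \code{\link{stat_map}} of kind \code{"ALE"}.
#' @param null an \code{ale_null} from \code{\link{mc_null}}.
#' @param q FDR level; default 0.05.
#' @return List: \code{binary} (surviving-voxel \code{stat_map}), \code{p}
#'   (per-voxel p map), \code{threshold} (smallest surviving ALE value, or
#'   \code{NA} when nothing survives).
#' @export
threshold_fdr <- function(ale, null, q = 0.05) {
  mask <- ale$grid$mask
  p <- null_pvalue(null, ale$values[mask])
  padj <- stats::p.adjust(p, method = "BH")
  surv <- padj <= q
  parr <- array(1, ale$grid$dim); parr[mask] <- p
  barr <- array(0, ale$grid$dim); barr[mask] <- as.numeric(surv)
  list(binary = stat_map(ale$grid, barr, kind = "binary"),
       p = stat_map(ale$grid, parr, kind = "p"),
       threshold = if (any(surv)) min(ale$values[mask][surv]) else NA_real_)
}

#' Uncorrected p thresholding of an ALE map
#'
#' Zeroes voxels whose empirical null p-value is not below \code{p_thresh};
#' the per-dataset pre-threshold applied to each input map before a
#' conjunction.
#'
#' @param ale an ALE \code{\link{stat_map}}.
#' @param null an \code{ale_null}.
#' @param p_thresh uncorrected voxel-wise level; default 0.05.
#' @return The thresholded ALE \code{stat_map} (surviving voxels keep their
#'   ALE value).
#' @export
threshold_uncorrected <- function(ale, null, p_thresh = 0.05) {
  mask <- ale$grid$mask
  p <- null_pvalue(null, ale$values[mask])
  keep <- p < p_thresh
  vv <- ale$values; vv[mask][!keep] <- 0
  stat_map(ale$grid, vv, kind = "ALE")
}

#' Cluster-extent thresholding
#'
#' Removes connected components of a binary map whose volume does not exceed
#' \code{min_volume_mm3} ("exceeding": strictly greater than).
#'
#' @param binary a binary \code{\link{stat_map}}.
#' @param min_volume_mm3 minimum component volume, mm^3; default 300.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A binary \code{stat_map} with small components zeroed.
#' @export
extent_threshold <- function(binary, min_volume_mm3 = 300, connectivity = 26) {
  lab <- label_components(binary, connectivity)
  if (max(lab) == 0) return(stat_map(binary$grid, array(0, binary$grid$dim),
                                     kind = "binary"))
  voxvol <- binary$grid$voxel_size^3
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * voxvol > min_volume_mm3)
  out <- array(0, binary$grid$dim)
  out[lab %in% keep] <- 1
  stat_map(binary$grid, out, kind = "binary")
}

#' Minimum-statistic conjunction of two maps
#'
#' Voxel-wise minimum of two maps on a shared grid. For thresholded ALE maps
#' this is the conjunction image: non-zero exactly where both inputs are.
#'
#' @param map_a,map_b \code{\link{stat_map}}s on the same grid.
#' @return A \code{stat_map} of the same kind as \code{map_a}.
#' @export
conjunction <- function(map_a, map_b) {
  .check_same_grid(map_a, map_b)
  stat_map(map_a$grid, pmin(map_a$values, map_b$values), kind = map_a$kind)
}

#' Suprathreshold cluster table
#'
#' Summarises the connected components of a thresholded map: volume in mm^3,
#' ALE-weighted centre of mass in mm, and the peak ALE value with its
#' location. Rows are ordered by decreasing volume.
#'
#' @param binary a binary \code{\link{stat_map}} (or any map whose nonzero
#'   voxels define the clusters).
#' @param ale the ALE \code{stat_map} supplying the weights and extrema.
#' @param connectivity component connectivity; default 26.
#' @return Data frame: \code{cluster}, \code{n_voxels}, \code{volume_mm3},
#'   \code{wc_x/y/z} (weighted centre), \code{peak_ale},
#'   \code{peak_x/y/z}.
#' @export
ale_cluster_report <- function(binary, ale, connectivity = 26) {
  .check_same_grid(binary, ale)
  lab <- label_components(binary, connectivity)
  ncl <- max(lab)
  if (ncl == 0)
    return(data.frame(cluster = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), wc_x = numeric(0),
                      wc_y = numeric(0), wc_z = numeric(0),
                      peak_ale = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0)))
  voxvol <- binary$grid$voxel_size^3
  rows <- lapply(seq_len(ncl), function(cl) {
    idx <- which(lab == cl)
    mm <- vox_to_mm(binary$grid, arrayInd(idx, binary$grid$dim))
    w <- ale$values[idx]
    if (sum(w) <= 0) w <- rep(1, length(idx))
    wc <- colSums(mm * w) / sum(w)
    pk <- which.max(ale$values[idx])
    data.frame(cluster = cl, n_voxels = length(idx),
               volume_mm3 = length(idx) * voxvol,
               wc_x = wc[1], wc_y = wc[2], wc_z = wc[3],
               peak_ale = ale$values[idx][pk],
               peak_x = mm[pk, 1], peak_y = mm[pk, 2], peak_z = mm[pk, 3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$volume_mm3), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Validate clusters against a thresholded map
#'
#' Marks each cluster of a clustering solution as validated when any
#' surviving voxel of the thresholded map lies within \code{radius_mm} of the
#' cluster centroid — the map-intersection cross-validation used when the
#' composition test is unavailable (single-class datasets).
#'
#' @param solution a \code{cluster_solution}.
#' @param validated a binary \code{\link{stat_map}} of surviving voxels.
#' @param radius_mm validation radius; default 5 (the clustering resolution).
#' @return The solution's \code{summaries} with a logical \code{validated}
#'   column appended.
#' @export
intersect_with_clusters <- function(solution, validated, radius_mm = 5) {
  stopifnot(inherits(solution, "cluster_solution"))
  idx <- which(validated$values != 0)
  summ <- solution$summaries
  if (length(idx) == 0) {
    summ$validated <- FALSE
    return(summ)
  }
  mm <- vox_to_mm(validated$grid, arrayInd(idx, validated$grid$dim))
  cent <- as.matrix(summ[, c("x", "y", "z")])
  summ$validated <- vapply(seq_len(nrow(cent)), function(i) {
    d2 <- colSums((t(mm) - cent[i, ])^2)
    any(d2 <= radius_mm^2)
  }, logical(1))
  summ
}

#' ALE conjunction analysis of two foci datasets
#'
#' Runs the full conjunction pipeline on two sets of experiments: builds
#' per-experiment MA maps and each dataset's ALE map, pre-thresholds each ALE
#' map at an uncorrected voxel-wise p (against its own Monte-Carlo null),
#' forms the minimum-statistic conjunction image, and applies FDR (pID) plus
#' cluster-extent thresholding to the conjunction. With
#' \code{order = "min_first"} the conjunction of the raw ALE maps is formed
#' before any thresholding and the uncorrected pre-threshold is skipped.
#'
#' @param foci_a,foci_b lists of per-experiment focus matrices (n x 3, mm).
#' @param grid a \code{\link{volume_grid}}.
#' @param fwhm_mm kernel FWHM; default 10.
#' @param pre_p per-dataset uncorrected threshold; default 0.05.
#' @param q FDR level on the conjunction; default 0.05.
#' @param min_volume_mm3 extent threshold; default 300.
#' @param n_iter Monte-Carlo iterations per null; default 200.
#' @param seed integer seed (nulls use \code{seed} and \code{seed + 1}; the
#'   conjunction null pools both designs under \code{seed + 2}).
#' @param order \code{"threshold_first"} (default) or \code{"min_first"}.
#' @return List: \code{ale_a}, \code{ale_b}, \code{conjunction} (ALE-valued),
#'   \code{surviving} (binary map after FDR + extent), \code{clusters}
#'   (cluster table of the surviving map), \code{nulls}.
#' @export
ale_conjunction <- function(foci_a, foci_b, grid, fwhm_mm = 10,
                            pre_p = 0.05, q = 0.05, min_volume_mm3 = 300,
                            n_iter = 200, seed = 1L,
                            order = c("threshold_first", "min_first")) {
  order <- match.arg(order)
  ale_a <- ale_union(lapply(foci_a, ma_map, grid = grid, fwhm_mm = fwhm_mm))
  ale_b <- ale_union(lapply(foci_b, ma_map, grid = grid, fwhm_mm = fwhm_mm))
  null_a <- mc_null(vapply(foci_a, nrow, 1L), grid, fwhm_mm, n_iter, seed)
  null_b <- mc_null(vapply(foci_b, nrow, 1L), grid, fwhm_mm, n_iter, seed + 1L)
  if (order == "threshold_first") {
    conj <- conjunction(threshold_uncorrected(ale_a, null_a, pre_p),
                        threshold_uncorrected(ale_b, null_b, pre_p))
  } else {
    conj <- conjunction(ale_a, ale_b)
  }
  ## null for the conjunction statistic: min of the two datasets' ALE under
  ## independent randomisation of both designs
  null_conj <- mc_null_conjunction(vapply(foci_a, nrow, 1L),
                                   vapply(foci_b, nrow, 1L),
                                   grid, fwhm_mm, n_iter, seed + 2L)
  fdr <- threshold_fdr(conj, null_conj, q)
  surviving <- extent_threshold(fdr$binary, min_volume_mm3)
  list(ale_a = ale_a, ale_b = ale_b, conjunction = conj,
       fdr_p = fdr$p, surviving = surviving,
       clusters = ale_cluster_report(surviving, conj),
       nulls = list(a = null_a, b = null_b, conjunction = null_conj))
}

#' Monte-Carlo null for a conjunction of two ALE maps
#'
#' Same randomisation scheme as \code{\link{mc_null}}, but each iteration
#' relocates both designs' foci and pools the voxel-wise MINIMUM of the two
#' ALE maps.
#'
#' @inheritParams mc_null
#' @param foci_design_a,foci_design_b per-experiment focus counts of the two
#'   datasets.
#' @return An \code{ale_null}.
#' @export
mc_null_conjunction <- function(foci_design_a, foci_design_b, grid,
                                fwhm_mm = 10, n_iter = 200, seed = 1L,
                                n_bins = 4096) {
  if (n_iter < 100) stop("n_iter must be at least 100")
  mask_idx <- which(grid$mask)
  if (length(mask_idx) == 0) stop("grid mask is empty")
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kmax <- (2 * pi * sigma^2)^(-1.5) * grid$voxel_size^3
  vmax <- 1 - (1 - kmax)^max(length(foci_design_a), length(foci_design_b))
  breaks <- seq(0, vmax * (1 + 1e-9), length.out = n_bins + 1)
  counts <- numeric(n_bins)
  vs <- grid$voxel_size
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  rand_ale <- function(design) {
    mas <- lapply(design, function(nf) {
      vox <- arrayInd(sample(mask_idx, nf, replace = TRUE), grid$dim)
      jit <- matrix(stats::runif(3 * nf, -0.5, 0.5), ncol = 3)
      ma_map(vox_to_mm(grid, vox) + jit * vs, grid, fwhm_mm)
    })
    ale_union(mas)$values[mask_idx]
  }
  for (it in seq_len(n_iter)) {
    v <- pmin(rand_ale(foci_design_a), rand_ale(foci_design_b))
    bins <- findInterval(v, breaks, left.open = TRUE, rightmost.closed = TRUE)
    bins <- pmax(1L, pmin(length(counts), bins))
    counts <- counts + tabulate(bins, nbins = length(counts))
  }
  structure(list(breaks = breaks, counts = counts, n_total = sum(counts),
                 upper_max = NA_real_, n_iter = n_iter, seed = seed,
                 foci_design = list(a = foci_design_a, b = foci_design_b)),
            class = "ale_null")
}
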