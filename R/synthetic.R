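#' Design for a synthetic foci dataset
#'
#' Describes a planted-truth foci dataset: a set of blob centres with
#' per-axis Gaussian spreads, per-centre focus counts and class labels, plus
#' uniformly scattered background foci carrying the remaining labels. Label
#' totals are exact by construction: each planted centre draws all of its
#' labels from its own class (pure enrichment) and the background carries
#' whatever remains of the per-class totals, randomly interleaved.
#'
#' @param centers k x 3 matrix of blob centres (MNI mm).
#' @param center_sd per-axis sd of each blob: scalar, 3-vector, or k x 3
#'   matrix (mm).
#' @param center_size integer vector of per-blob focus counts.
#' @param center_label character vector: each blob's class.
#' @param label_totals named integer vector: exact total count per class
#'   across the whole dataset (must dominate the planted counts).
#' @param n_studies number of study ids to assign round-robin; default 31.
#' @param bbox 2 x 3 mm bounding box for background foci; default the brain
#'   box used by \code{\link{volume_grid}}.
#' @return An object of class \code{foci_design}.
#' @export
foci_design <- function(centers, center_sd, center_size, center_label,
                        label_totals, n_studies = 31,
                        bbox = rbind(c(-70, -100, -50), c(70, 70, 80))) {
  centers <- .as_point_matrix(centers)
  k <- nrow(centers)
  if (is.null(dim(center_sd)))
    center_sd <- matrix(center_sd, k, 3, byrow = (length(center_sd) == 3))
  stopifnot(nrow(center_sd) == k, ncol(center_sd) == 3,
            length(center_size) == k, length(center_label) == k,
            all(center_size >= 1), all(center_sd >= 0))
  planted <- tapply(center_size, center_label, sum)
  for (l in names(planted)) {
    if (is.na(label_totals[l]) || label_totals[l] < planted[[l]])
      stop("label_totals must cover the planted counts for label ", l)
  }
  structure(list(centers = centers, center_sd = center_sd,
                 center_size = as.integer(center_size),
                 center_label = as.character(center_label),
                 label_totals = label_totals, n_studies = as.integer(n_studies),
                 bbox = bbox),
            class = "foci_design")
}

#' Default action-awareness foci design
#'
#' The full-scale benchmark design: 342 foci with exactly 246 "intention"
#' and 96 "self_agency" labels; nine pure planted blobs (five intention, four
#' self-agency) at plausible, well-separated MNI sites in the mesial frontal
#' wall, insula, parietal cortex, occipital cortex and cerebellum, with blob
#' sizes 10/17/9/9/13 and 5/7/5/5 and 4.5 mm per-axis spread; the remaining
#' 262 foci are uniform background over the brain box, carrying the left-over
#' labels (188 intention, 74 self-agency). 31 studies assigned round-robin.
#'
#' @return A \code{\link{foci_design}}.
#' @export
aa_foci_design <- function() {
  centers <- rbind(
    c(-3, 12, 53),   # pre-SMA            (intention)
    c(1, 19, 39),    # middle cingulum    (intention)
    c(-41, 17, -2),  # anterior insula    (intention)
    c(18, -67, 52),  # sup. parietal      (intention)
    c(39, -45, 41),  # inf. parietal      (intention)
    c(-7, -4, 69),   # SMA proper         (self-agency)
    c(-41, 2, 1),    # posterior insula   (self-agency)
    c(18, -90, -1),  # calcarine          (self-agency)
    c(24, -53, -27)) # cerebellum         (self-agency)
  foci_design(centers,
              center_sd = 4.5,
              center_size = c(10, 17, 9, 9, 13, 5, 7, 5, 5),
              center_label = c(rep("intention", 5), rep("self_agency", 4)),
              label_totals = c(intention = 246, self_agency = 96))
}

#' Generate a synthetic foci dataset with planted truth
#'
#' Draws each planted blob's foci from axis-aligned Gaussians around its
#' centre, scatters the background uniformly in the design's bounding box,
#' permutes the background labels, and assigns study ids round-robin over the
#' shuffled dataset. Deterministic given the seed.
#'
#' @param design a \code{\link{foci_design}}.
#' @param seed integer seed.
#' @return List: \code{dataset} (a \code{\link{foci_dataset}}) and
#'   \code{truth} (list with per-focus \code{center} assignment, 0 =
#'   background, plus the design).
#' @export
generate_foci <- function(design, seed = 1L) {
  stopifnot(inherits(design, "foci_design"))
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  k <- nrow(design$centers)
  blobs <- lapply(seq_len(k), function(i) {
    n <- design$center_size[i]
    xyz <- matrix(stats::rnorm(3 * n,
                               mean = rep(design$centers[i, ], each = n),
                               sd = rep(design$center_sd[i, ], each = n)),
                  ncol = 3)
    data.frame(label = design$center_label[i],
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], center = i,
               stringsAsFactors = FALSE)
  })
  planted <- do.call(rbind, blobs)
  remaining <- design$label_totals
  for (l in unique(planted$label))
    remaining[l] <- remaining[l] - sum(planted$label == l)
  n_bg <- sum(remaining)
  bg <- NULL
  if (n_bg > 0) {
    bg_labels <- sample(rep(names(remaining), remaining))
    bg <- data.frame(label = bg_labels,
                     x = stats::runif(n_bg, design$bbox[1, 1], design$bbox[2, 1]),
                     y = stats::runif(n_bg, design$bbox[1, 2], design$bbox[2, 2]),
                     z = stats::runif(n_bg, design$bbox[1, 3], design$bbox[2, 3]),
                     center = 0L, stringsAsFactors = FALSE)
  }
  all_foci <- rbind(planted, bg)
  ord <- sample(nrow(all_foci))
  all_foci <- all_foci[ord, ]
  n <- nrow(all_foci)
  study <- paste0("study", rep_len(seq_len(design$n_studies), n))
  df <- data.frame(study = study,
                   contrast = paste0(study, "_c1"),
                   label = all_foci$label,
                   x = all_foci$x, y = all_foci$y, z = all_foci$z,
                   space = "MNI", stringsAsFactors = FALSE)
  ds <- foci_dataset(df, label_set = sort(names(design$label_totals)),
                     provenance = sprintf("synthetic (seed %d)", seed))
  list(dataset = ds,
       truth = list(center = all_foci$center, design = design, seed = seed))
}

#' Design for synthetic preprocessed BOLD runs
#'
#' Describes a planted seed-to-voxel connectivity experiment: a grid, a seed
#' region, and connected regions whose voxel series correlate with the seed
#' time course at a planted level rho. Everything downstream of acquisition
#' and preprocessing is emulated directly: series are white Gaussian noise
#' with the planted correlation structure, nothing else.
#'
#' @param grid a \code{\link{volume_grid}} (desk-scale grids are fine).
#' @param T_len time points per run; default 202 (212 acquired volumes with
#'   the first 10 discarded).
#' @param n_subjects subjects per group; default 32.
#' @param seed_center,seed_radius seed sphere (mm).
#' @param regions list of planted regions, each a list with \code{voxels}
#'   (linear indices) and \code{rho} (correlation with the seed, in (-1, 1)).
#' @param noise_sd background noise sd; default 1.
#' @return An object of class \code{bold_design}.
#' @export
bold_design <- function(grid, T_len = 202, n_subjects = 32,
                        seed_center = c(0, 0, 0), seed_radius = 5,
                        regions = list(), noise_sd = 1) {
  stopifnot(inherits(grid, "volume_grid"), T_len >= 20, n_subjects >= 1)
  for (r in regions)
    stopifnot(length(r$voxels) >= 1, abs(r$rho) < 1)
  structure(list(grid = grid, T_len = as.integer(T_len),
                 n_subjects = as.integer(n_subjects),
                 seed = seed_roi(seed_center, seed_radius),
                 regions = regions, noise_sd = noise_sd),
            class = "bold_design")
}

#' Generate synthetic BOLD runs with planted connectivity
#'
#' For each subject: the seed voxels share a unit-variance Gaussian seed
#' time course (plus voxel-level noise is NOT added inside the seed, so the
#' seed's mean series is the planted course); each planted-region voxel is
#' \eqn{\rho \cdot s + \sqrt{1-\rho^2}\,\epsilon} with white unit noise
#' \eqn{\epsilon}; every other voxel is independent noise with sd
#' \code{noise_sd}. Per-subject seeds are \code{seed + subject index}, so
#' single runs are reproducible in isolation.
#'
#' @param design a \code{\link{bold_design}}.
#' @param seed base integer seed.
#' @return List: \code{runs} (list of \code{\link{bold_run}}s) and
#'   \code{truth} (planted regions + design + seeds).
#' @export
generate_bold <- function(design, seed = 1L) {
  stopifnot(inherits(design, "bold_design"))
  grid <- design$grid
  nvox <- prod(grid$dim)
  seed_idx <- roi_voxels(design$seed, grid)
  subject_seeds <- seed + seq_len(design$n_subjects)
  runs <- lapply(seq_len(design$n_subjects), function(s) {
    old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
    set.seed(subject_seeds[s])
    ts <- stats::rnorm(design$T_len)
    series <- matrix(stats::rnorm(nvox * design$T_len, sd = design$noise_sd),
                     nvox, design$T_len)
    series[seed_idx, ] <- matrix(ts, length(seed_idx), design$T_len,
                                 byrow = TRUE)
    for (r in design$regions) {
      eps <- matrix(stats::rnorm(length(r$voxels) * design$T_len),
                    length(r$voxels), design$T_len)
      series[r$voxels, ] <- r$rho * matrix(ts, length(r$voxels),
                                           design$T_len, byrow = TRUE) +
        sqrt(1 - r$rho^2) * eps
    }
    bold_run(grid, series, subject_id = sprintf("sub%02d", s))
  })
  list(runs = runs,
       truth = list(design = design, seed = seed,
                    subject_seeds = subject_seeds, seed_voxels = seed_idx))
}
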