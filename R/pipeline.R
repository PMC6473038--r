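#' Read a pipeline run configuration
#'
#' Run configurations are YAML files of scalar keys. Missing keys fall back
#' to defaults; unknown keys are kept (stages may consume them). All
#' randomness in a run derives from \code{seed}.
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @param ... named overrides applied after file and defaults.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    seed = 1L,
    out_dir = "results",
    foci = NULL,              # path to a foci TSV (cluster/compose/ale input)
    resolution_mm = 5,
    criterion = "mean",
    alpha = 0.05,
    voxel_size = 4,
    fwhm_mm = 10,
    n_iter = 200,
    pre_p = 0.05,
    fdr_q = 0.05,
    extent_mm3 = 300,
    conj_order = "threshold_first",
    voxel_p = 0.001,
    cluster_fwe = 0.05,
    n_perm = 500,
    n_subjects = 32,
    T_len = 202,
    rho = 0.6)
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (key in c("resolution_mm", "alpha", "fwhm_mm", "pre_p", "fdr_q",
                "voxel_p", "cluster_fwe"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0)
      stop("invalid config field '", key, "': must be a positive number")
  for (key in c("alpha", "pre_p", "fdr_q", "voxel_p", "cluster_fwe"))
    if (cfg[[key]] > 1) stop("invalid config field '", key, "': must be <= 1")
  if (cfg$n_iter < 100) stop("invalid config field 'n_iter': must be >= 100")
  structure(cfg, class = c("run_config", "list"))
}

.write_manifest <- function(out_dir, stage, cfg, artifacts) {
  manifest <- list(stage = stage,
                   package = "focimeta",
                   version = as.character(utils::packageVersion("focimeta")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = cfg[setdiff(names(cfg), "out_dir")],
                   artifacts = artifacts)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

.pipeline_grid <- function(cfg) volume_grid(voxel_size = cfg$voxel_size)

.load_foci <- function(cfg, out_dir) {
  path <- cfg$foci %||% file.path(out_dir, "foci.tsv")
  if (!file.exists(path))
    stop("foci table not found at '", path,
         "'; run the simulate stage or set config field 'foci'")
  read_foci_table(path)
}

.cluster_from_foci <- function(ds, cfg) {
  lk <- ward_linkage(ds)
  cut_at_resolution(lk, resolution_mm = cfg$resolution_mm,
                    criterion = cfg$criterion, labels = ds$label)
}

#' Run one pipeline stage
#'
#' Orchestrates the end-to-end analysis as re-runnable stages, each writing
#' its TSV/NIfTI artifacts plus a JSON manifest (parameters, seeds, package
#' version) under the configured output directory:
#' \describe{
#'   \item{simulate}{synthetic foci dataset from the default design
#'     (\code{foci.tsv}, \code{truth.json});}
#'   \item{cluster}{Ward clustering with the resolution cut
#'     (\code{clusters.tsv}, per-focus \code{assignments.tsv});}
#'   \item{compose}{binomial composition test (\code{composition.tsv});}
#'   \item{ale}{per-class ALE maps over contrasts (\code{ale_<label>.nii.gz});}
#'   \item{conjoin}{thresholded ALE conjunction of the two largest classes
#'     (\code{conjunction_clusters.tsv}, \code{surviving.nii.gz});}
#'   \item{validate}{intersection of the clustering solution with the
#'     surviving conjunction map (\code{validated.tsv});}
#'   \item{connect}{synthetic resting-state runs, two seeds, paired contrasts
#'     both ways plus the conjunction of simple effects
#'     (\code{connectivity_*.tsv/.nii.gz}).}
#' }
#' Deterministic stages re-run to identical artifacts under the same config.
#'
#' @param config a \code{\link{run_config}} (or a YAML path).
#' @param stage one of \code{"simulate"}, \code{"cluster"}, \code{"compose"},
#'   \code{"ale"}, \code{"conjoin"}, \code{"validate"}, \code{"connect"}.
#' @param out_dir output directory override.
#' @param seed seed override.
#' @return Invisibly, the stage's main result object; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), stage, out_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- run_config(config)
  stage <- match.arg(stage, c("simulate", "cluster", "compose", "ale",
                              "conjoin", "validate", "connect"))
  cfg <- config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(stage,
    simulate = .stage_simulate(cfg),
    cluster = .stage_cluster(cfg),
    compose = .stage_compose(cfg),
    ale = .stage_ale(cfg),
    conjoin = .stage_conjoin(cfg),
    validate = .stage_validate(cfg),
    connect = .stage_connect(cfg))
  invisible(out)
}

.stage_simulate <- function(cfg) {
  gen <- generate_foci(aa_foci_design(), seed = cfg$seed)
  fp <- file.path(cfg$out_dir, "foci.tsv")
  write_foci_table(gen$dataset, fp)
  tp <- file.path(cfg$out_dir, "truth.json")
  jsonlite::write_json(list(center = gen$truth$center,
                            centers = gen$truth$design$centers,
                            center_label = gen$truth$design$center_label,
                            seed = cfg$seed),
                       tp, auto_unbox = TRUE)
  .write_manifest(cfg$out_dir, "simulate", cfg, c(fp, tp))
  gen
}

.stage_cluster <- function(cfg) {
  ds <- .load_foci(cfg, cfg$out_dir)
  sol <- .cluster_from_foci(ds, cfg)
  cp <- file.path(cfg$out_dir, "clusters.tsv")
  write_cluster_report(sol, cp)
  ap <- file.path(cfg$out_dir, "assignments.tsv")
  utils::write.table(data.frame(focus = seq_along(sol$assignment),
                                cluster = sol$assignment),
                     ap, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(cfg$out_dir, "cluster", cfg, c(cp, ap))
  sol
}

.stage_compose <- function(cfg) {
  ds <- .load_foci(cfg, cfg$out_dir)
  sol <- .cluster_from_foci(ds, cfg)
  comp <- composition_test(sol, dataset_priors(ds), alpha = cfg$alpha)
  pp <- file.path(cfg$out_dir, "composition.tsv")
  write_cluster_report(comp, pp)
  .write_manifest(cfg$out_dir, "compose", cfg, pp)
  comp
}

.by_contrast <- function(ds, label) {
  sub <- as.data.frame(ds)[ds$label == label, ]
  lapply(split(sub, paste(sub$study, sub$contrast)),
         function(d) as.matrix(d[, c("x", "y", "z")]))
}

.top_labels <- function(ds) {
  tab <- sort(table(ds$label), decreasing = TRUE)
  if (length(tab) < 2) stop("conjunction stages need at least two classes")
  names(tab)[1:2]
}

.stage_ale <- function(cfg) {
  ds <- .load_foci(cfg, cfg$out_dir)
  grid <- .pipeline_grid(cfg)
  paths <- character(0)
  maps <- list()
  for (l in unique(ds$label)) {
    exp_foci <- .by_contrast(ds, l)
    ale <- ale_union(lapply(exp_foci, ma_map, grid = grid,
                            fwhm_mm = cfg$fwhm_mm))
    p <- file.path(cfg$out_dir, paste0("ale_", l, ".nii.gz"))
    write_stat_map(ale, p)
    paths <- c(paths, p)
    maps[[l]] <- ale
  }
  .write_manifest(cfg$out_dir, "ale", cfg, paths)
  maps
}

.stage_conjoin <- function(cfg) {
  ds <- .load_foci(cfg, cfg$out_dir)
  grid <- .pipeline_grid(cfg)
  labs <- .top_labels(ds)
  res <- ale_conjunction(.by_contrast(ds, labs[1]), .by_contrast(ds, labs[2]),
                         grid, fwhm_mm = cfg$fwhm_mm, pre_p = cfg$pre_p,
                         q = cfg$fdr_q, min_volume_mm3 = cfg$extent_mm3,
                         n_iter = cfg$n_iter, seed = cfg$seed,
                         order = cfg$conj_order)
  sp <- file.path(cfg$out_dir, "surviving.nii.gz")
  write_stat_map(res$surviving, sp)
  tp <- file.path(cfg$out_dir, "conjunction_clusters.tsv")
  utils::write.table(res$clusters, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_manifest(cfg$out_dir, "conjoin", cfg, c(sp, tp))
  res
}

.stage_validate <- function(cfg) {
  ds <- .load_foci(cfg, cfg$out_dir)
  sol <- .cluster_from_foci(ds, cfg)
  sp <- file.path(cfg$out_dir, "surviving.nii.gz")
  if (!file.exists(sp)) stop("no surviving map found; run the conjoin stage")
  surv <- read_stat_map(sp, kind = "binary")
  val <- intersect_with_clusters(sol, surv, radius_mm = cfg$resolution_mm)
  vp <- file.path(cfg$out_dir, "validated.tsv")
  utils::write.table(val, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(cfg$out_dir, "validate", cfg, vp)
  val
}

.stage_connect <- function(cfg) {
  grid <- volume_grid(voxel_size = cfg$voxel_size,
                      bbox = rbind(c(-30, -30, -14), c(30, 30, 14)))
  ## two seeds on the mesial wall of the toy grid; each with its own planted
  ## network, plus one region shared by both
  seed_a <- c(-2, 12, 10); seed_b <- c(-6, -4, 10)
  region <- function(center, radius) roi_voxels(seed_roi(center, radius), grid)
  reg_a <- region(c(20, 20, 0), 6)
  reg_b <- region(c(-20, -20, 0), 6)
  reg_shared <- region(c(0, -24, 8), 6)
  za <- zb <- vector("list", cfg$n_subjects)
  for (which_seed in c("a", "b")) {
    ctr <- if (which_seed == "a") seed_a else seed_b
    own <- if (which_seed == "a") reg_a else reg_b
    des <- bold_design(grid, T_len = cfg$T_len, n_subjects = cfg$n_subjects,
                       seed_center = ctr, seed_radius = 5,
                       regions = list(list(voxels = own, rho = cfg$rho),
                                      list(voxels = reg_shared, rho = cfg$rho)))
    gen <- generate_bold(des, seed = cfg$seed +
                           (if (which_seed == "a") 0L else 10000L))
    zmaps <- lapply(gen$runs, function(run)
      fisher_z(correlation_map(run, seed_series(run, des$seed))))
    if (which_seed == "a") za <- zmaps else zb <- zmaps
  }
  res_ab <- paired_contrast(za, zb, voxel_p = cfg$voxel_p,
                            cluster_fwe = cfg$cluster_fwe,
                            n_perm = cfg$n_perm, seed = cfg$seed + 1L)
  res_ba <- paired_contrast(zb, za, voxel_p = cfg$voxel_p,
                            cluster_fwe = cfg$cluster_fwe,
                            n_perm = cfg$n_perm, seed = cfg$seed + 2L)
  simp_a <- paired_contrast(za, NULL, voxel_p = cfg$voxel_p,
                            cluster_fwe = cfg$cluster_fwe,
                            n_perm = cfg$n_perm, seed = cfg$seed + 3L)
  simp_b <- paired_contrast(zb, NULL, voxel_p = cfg$voxel_p,
                            cluster_fwe = cfg$cluster_fwe,
                            n_perm = cfg$n_perm, seed = cfg$seed + 4L)
  conj <- conjunction_simple_effects(simp_a, simp_b)
  arts <- character(0)
  for (nm in c("a_gt_b", "b_gt_a")) {
    r <- if (nm == "a_gt_b") res_ab else res_ba
    tp <- file.path(cfg$out_dir, paste0("connectivity_", nm, ".tsv"))
    utils::write.table(r$clusters, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    np <- file.path(cfg$out_dir, paste0("connectivity_", nm, "_t.nii.gz"))
    write_stat_map(r$t, np)
    arts <- c(arts, tp, np)
  }
  cp <- file.path(cfg$out_dir, "connectivity_conjunction.nii.gz")
  write_stat_map(conj, cp)
  arts <- c(arts, cp)
  .write_manifest(cfg$out_dir, "connect", cfg, arts)
  list(a_gt_b = res_ab, b_gt_a = res_ba, simple_a = simp_a,
       simple_b = simp_b, conjunction = conj,
       truth = list(region_a = reg_a, region_b = reg_b,
                    region_shared = reg_shared))
}
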