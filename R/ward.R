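#' Ward agglomerative linkage of 3-D foci
#'
#' Performs agglomerative hierarchical clustering of point coordinates under
#' Ward's minimum-variance criterion. The cost of merging clusters A and B is
#' the increase in within-cluster sum of squared deviations,
#' \deqn{\Delta(A,B) = \frac{|A||B|}{|A|+|B|} \, \lVert c_A - c_B \rVert^2,}
#' computed directly from cluster sizes and centroids; at every step the pair
#' with the smallest cost is merged. Ties are broken deterministically in
#' favour of the pair with the lexicographically smallest cluster indices in
#' input order, so the merge sequence is a pure function of the input.
#'
#' @param points an n x 3 numeric matrix of coordinates (mm), or anything
#'   coercible to one.
#' @return An object of class \code{ward_linkage}: a list with
#'   \describe{
#'     \item{merge}{(n-1) x 2 integer matrix in \code{\link[stats]{hclust}}
#'       convention (negative entries are singleton observations, positive
#'       entries earlier merge rows);}
#'     \item{cost}{the Ward objective increase (mm^2) of each merge,
#'       non-decreasing;}
#'     \item{sizes}{focus count of the cluster formed at each merge;}
#'     \item{points}{the input coordinates;}
#'     \item{hclust}{an equivalent \code{hclust} object (heights = costs).}
#'   }
#' @export
ward_linkage <- function(points) {
  pts <- .as_point_matrix(points)
  n <- nrow(pts)
  if (n < 1L) stop("ward_linkage needs at least one point")
  if (n == 1L) {
    h <- structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                        order = 1L, labels = NULL, method = "ward",
                        call = match.call(), dist.method = "euclidean"),
                   class = "hclust")
    return(structure(list(merge = matrix(integer(0), 0, 2), cost = numeric(0),
                          sizes = integer(0), points = pts, hclust = h),
                     class = "ward_linkage"))
  }
  ## Active-cluster state: centroids, sizes, hclust id (-obs or +merge row)
  cent <- pts
  size <- rep(1L, n)
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  ## cost matrix, upper triangle (i < j); inactive = Inf
  d2 <- as.matrix(stats::dist(pts))^2
  cost <- d2 / 2
  cost[lower.tri(cost, diag = TRUE)] <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  costs <- numeric(n - 1L)
  sizes <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    ## lexicographically first (i, j) among the minima
    m <- min(cost)
    hits <- which(cost == m, arr.ind = TRUE)
    pick <- hits[order(hits[, 1], hits[, 2])[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    merge[step, ] <- c(id[i], id[j])
    costs[step] <- m
    ni <- size[i]; nj <- size[j]
    sizes[step] <- ni + nj
    cent[i, ] <- (ni * cent[i, ] + nj * cent[j, ]) / (ni + nj)
    size[i] <- ni + nj
    id[i] <- step
    active[j] <- FALSE
    cost[j, ] <- Inf; cost[, j] <- Inf
    ## refresh costs of the merged cluster against all other active clusters
    others <- which(active); others <- others[others != i]
    if (length(others) > 0) {
      dd <- sweep(cent[others, , drop = FALSE], 2, cent[i, ])
      new_cost <- size[i] * size[others] / (size[i] + size[others]) *
        rowSums(dd^2)
      lo <- pmin(others, i); hi <- pmax(others, i)
      cost[cbind(lo, hi)] <- new_cost
    }
  }
  h <- structure(list(merge = merge, height = costs, order = .dendro_order(merge),
                      labels = NULL, method = "ward",
                      call = match.call(), dist.method = "euclidean"),
                 class = "hclust")
  structure(list(merge = merge, cost = costs, sizes = sizes,
                 points = pts, hclust = h),
            class = "ward_linkage")
}

.as_point_matrix <- function(points) {
  if (inherits(points, "foci_dataset"))
    points <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3 || any(!is.finite(pts)))
    stop("points must be a finite n x 3 matrix")
  pts
}

## leaf ordering for the hclust object (left-to-right dendrogram traversal)
.dendro_order <- function(merge) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  if (nrow(merge) == 0L) return(1L)
  as.integer(walk(nrow(merge)))
}

#' Cut a Ward dendrogram at a spatial resolution
#'
#' Chooses the coarsest partition on the dendrogram (fewest clusters) whose
#' mean per-cluster standard deviation does not exceed \code{resolution_mm}
#' on any of the three axes. Standard deviations use the sample (n-1)
#' denominator and are 0 for singletons; the mean is taken over all clusters,
#' singletons included. Since the all-singleton partition has mean sd 0, a
#' valid cut always exists. With \code{criterion = "max"} the rule is instead
#' that every individual cluster's per-axis sd stays within the resolution.
#'
#' @param linkage a \code{\link{ward_linkage}}.
#' @param resolution_mm spatial resolution in mm; default 5.
#' @param criterion \code{"mean"} (default): mean over clusters of per-axis sd
#'   \eqn{\le} resolution on each axis; \code{"max"}: per-cluster bound.
#' @param labels optional per-focus class labels; when given, per-cluster
#'   label counts are filled in (see \code{\link{summarize_clusters}}).
#' @return A \code{cluster_solution}: list with \code{assignment} (integer
#'   cluster id per focus, ids ordered by first appearance), \code{summaries}
#'   (per-cluster data frame: id, size, centroid, per-axis sd, label counts),
#'   \code{k} (number of clusters), \code{mean_sd} (the 3-vector of mean
#'   per-axis sds at the cut), \code{resolution_mm} and \code{criterion}.
#' @export
cut_at_resolution <- function(linkage, resolution_mm = 5,
                              criterion = c("mean", "max"), labels = NULL) {
  stopifnot(inherits(linkage, "ward_linkage"))
  criterion <- match.arg(criterion)
  if (!is.numeric(resolution_mm) || resolution_mm <= 0)
    stop("resolution_mm must be positive")
  pts <- linkage$points
  n <- nrow(pts)
  for (k in seq_len(n)) {
    assign_k <- if (n == 1L) 1L else stats::cutree(linkage$hclust, k = k)
    sds <- .per_cluster_axis_sd(pts, assign_k)
    stat <- if (criterion == "mean") colMeans(sds) else apply(sds, 2, max)
    if (all(stat <= resolution_mm)) {
      sol <- .build_solution(pts, assign_k, labels)
      sol$mean_sd <- colMeans(sds)
      sol$resolution_mm <- resolution_mm
      sol$criterion <- criterion
      return(sol)
    }
  }
  stop("internal error: no admissible cut found") # unreachable
}

## per-cluster per-axis sample sd (0 for singletons); rows = clusters
.per_cluster_axis_sd <- function(pts, assign) {
  ids <- sort(unique(assign))
  out <- matrix(0, length(ids), 3, dimnames = list(NULL, c("x", "y", "z")))
  for (a in seq_along(ids)) {
    m <- pts[assign == ids[a], , drop = FALSE]
    if (nrow(m) > 1L) out[a, ] <- apply(m, 2, stats::sd)
  }
  out
}

.build_solution <- function(pts, assign, labels = NULL) {
  ## relabel cluster ids by first appearance for stable reporting
  first <- match(unique(assign), assign)
  remap <- stats::setNames(seq_along(first), assign[first])
  assign <- as.integer(remap[as.character(assign)])
  ids <- seq_len(max(assign))
  summ <- do.call(rbind, lapply(ids, function(a) {
    m <- pts[assign == a, , drop = FALSE]
    sd3 <- if (nrow(m) > 1L) apply(m, 2, stats::sd) else c(0, 0, 0)
    data.frame(cluster = a, size = nrow(m),
               x = mean(m[, 1]), y = mean(m[, 2]), z = mean(m[, 3]),
               sd_x = sd3[1], sd_y = sd3[2], sd_z = sd3[3])
  }))
  sol <- structure(list(assignment = assign, summaries = summ,
                        k = length(ids), points = pts),
                   class = "cluster_solution")
  if (!is.null(labels)) sol <- summarize_clusters(sol, labels)
  sol
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: %d clusters over %d foci\n",
              x$k, length(x$assignment)))
  cat(sprintf("sizes: %s\n", paste(range(x$summaries$size), collapse = "-")))
  invisible(x)
}

#' Fill per-cluster label counts into a cluster solution
#'
#' @param solution a \code{cluster_solution}.
#' @param labels character vector of per-focus class labels, aligned with the
#'   points that were clustered.
#' @return The solution with one count column per label (named
#'   \code{n_<label>}) appended to \code{summaries}, rows sorted by cluster id.
#' @export
summarize_clusters <- function(solution, labels) {
  stopifnot(inherits(solution, "cluster_solution"))
  if (length(labels) != length(solution$assignment))
    stop("labels length (", length(labels),
         ") does not match number of foci (", length(solution$assignment), ")")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  counts <- table(cluster = solution$assignment,
                  label = factor(labels, levels = lev))
  cm <- matrix(as.integer(counts), nrow = nrow(counts),
               dimnames = list(rownames(counts), paste0("n_", lev)))
  summ <- solution$summaries[, !grepl("^n_", names(solution$summaries))]
  summ <- summ[order(summ$cluster), ]
  stopifnot(all(rowSums(cm) == summ$size))
  solution$summaries <- cbind(summ, cm[as.character(summ$cluster), , drop = FALSE])
  rownames(solution$summaries) <- NULL
  solution$labels <- labels
  solution$label_set <- lev
  solution
}

#' Write a cluster report table
#'
#' Writes the per-cluster summary (cluster id, size k, centroid x/y/z,
#' per-axis sd, and any label counts or composition columns) as TSV.
#'
#' @param solution a \code{cluster_solution} (or its \code{summaries} frame).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cluster_report <- function(solution, path) {
  df <- if (inherits(solution, "cluster_solution")) solution$summaries else solution
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
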