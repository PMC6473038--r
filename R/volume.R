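#' Construct a voxel grid aligned to MNI space
#'
#' A \code{volume_grid} carries the voxel lattice on which all maps live: the
#' array dimensions, an affine mapping 0-based voxel indices to MNI RAS mm,
#' and an inclusion mask. The default grid covers the standard MNI bounding
#' box [-90, 90] x [-126, 90] x [-72, 108] mm at 2 mm isotropic voxels with
#' an all-inclusive mask.
#'
#' @param voxel_size isotropic voxel edge, mm; default 2.
#' @param bbox 2 x 3 matrix: row 1 the minimum mm corner, row 2 the maximum.
#' @param mask optional logical array matching the grid dimensions.
#' @return An object of class \code{volume_grid}: list with \code{dim},
#'   \code{affine} (4 x 4), \code{voxel_size}, \code{mask}.
#' @export
volume_grid <- function(voxel_size = 2,
                        bbox = rbind(c(-90, -126, -72), c(90, 90, 108)),
                        mask = NULL) {
  stopifnot(voxel_size > 0, all(bbox[2, ] >= bbox[1, ]))
  dims <- as.integer(floor((bbox[2, ] - bbox[1, ]) / voxel_size)) + 1L
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- bbox[1, ]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  structure(list(dim = dims, affine = affine, voxel_size = voxel_size,
                 mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels at %g mm, %d in mask\n",
              paste(x$dim, collapse = " x "), x$voxel_size, sum(x$mask)))
  invisible(x)
}

#' Voxel indices to mm and back
#'
#' \code{vox_to_mm} maps 1-based voxel array indices (n x 3) to mm centre
#' coordinates through the grid affine; \code{mm_to_vox} is the inverse,
#' returning fractional indices (round to land on a voxel).
#'
#' @param grid a \code{\link{volume_grid}}.
#' @param vox n x 3 matrix of 1-based voxel indices.
#' @param mm n x 3 matrix of mm coordinates.
#' @return n x 3 numeric matrix.
#' @export
vox_to_mm <- function(grid, vox) {
  v <- .as_coord_matrix(vox)
  sweep((v - 1) %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4], `+`)
}

#' @rdname vox_to_mm
#' @export
mm_to_vox <- function(grid, mm) {
  m <- .as_coord_matrix(mm)
  sweep(m, 2, grid$affine[1:3, 4]) %*% t(solve(grid$affine[1:3, 1:3])) + 1
}

#' Construct a statistical map on a grid
#'
#' @param grid a \code{\link{volume_grid}}.
#' @param values numeric array matching \code{grid$dim} (or a scalar,
#'   recycled).
#' @param kind one of \code{"MA"}, \code{"ALE"}, \code{"p"}, \code{"z"},
#'   \code{"t"}, \code{"r"}, \code{"binary"}.
#' @return An object of class \code{stat_map}: list \code{grid},
#'   \code{values}, \code{kind}. Values outside the grid mask are zeroed
#'   (for \code{"p"} maps, set to 1).
#' @export
stat_map <- function(grid, values, kind = "ALE") {
  stopifnot(inherits(grid, "volume_grid"))
  kind <- match.arg(kind, c("MA", "ALE", "p", "z", "t", "r", "binary"))
  if (length(values) == 1) values <- array(values, grid$dim)
  stopifnot(identical(dim(values), grid$dim))
  fill <- if (kind == "p") 1 else 0
  values[!grid$mask] <- fill
  structure(list(grid = grid, values = values, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$grid$mask]
  cat(sprintf("stat_map[%s]: %s voxels, range %.4g..%.4g, %d nonzero\n",
              x$kind, paste(x$grid$dim, collapse = "x"),
              min(v), max(v), sum(v != 0)))
  invisible(x)
}

.check_same_grid <- function(a, b) {
  if (!identical(a$grid$dim, b$grid$dim) ||
      !isTRUE(all.equal(a$grid$affine, b$grid$affine)))
    stop("maps are not on the same grid")
}

#' Label connected components of a binary map
#'
#' Flood-fill labelling of the nonzero voxels of a binary map under a chosen
#' neighbourhood (26-connectivity by default, i.e. faces, edges and corners).
#'
#' @param map a binary \code{\link{stat_map}} (nonzero = foreground) or a
#'   logical/numeric array.
#' @param connectivity 6, 18 or 26; default 26.
#' @return Integer array of the same dimensions: 0 for background, components
#'   numbered 1, 2, ... in order of discovery (first-voxel array order).
#' @export
label_components <- function(map, connectivity = 26) {
  arr <- if (inherits(map, "stat_map")) map$values else map
  dims <- dim(arr)
  stopifnot(length(dims) == 3)
  fg <- which(arr != 0)
  labels <- array(0L, dims)
  if (length(fg) == 0L) return(labels)
  offs <- .neighbour_offsets(dims, connectivity)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  in_fg <- array(FALSE, dims); in_fg[fg] <- TRUE
  cur <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    labels[start] <- cur
    while (length(frontier) > 0L) {
      ## expand all frontier voxels at once; guard against wrap-around by
      ## checking neighbour coordinates explicitly
      fi <- arrayInd(frontier, dims)
      cand <- lapply(seq_len(nrow(offs)), function(o) {
        ni <- sweep(fi, 2, offs[o, ], `+`)
        ok <- ni[, 1] >= 1 & ni[, 1] <= nx & ni[, 2] >= 1 & ni[, 2] <= ny &
          ni[, 3] >= 1 & ni[, 3] <= nz
        if (!any(ok)) return(integer(0))
        ni <- ni[ok, , drop = FALSE]
        ni[, 1] + (ni[, 2] - 1L) * nx + (ni[, 3] - 1L) * nx * ny
      })
      cand <- unique(unlist(cand))
      cand <- cand[in_fg[cand] & labels[cand] == 0L]
      labels[cand] <- cur
      frontier <- cand
    }
  }
  labels
}

.neighbour_offsets <- function(dims, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  g[keep, , drop = FALSE]
}

#' Read and write maps as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti}. \code{write_stat_map} stores the values
#' with the grid affine in the sform; \code{read_stat_map} rebuilds the grid
#' from the header (mask all-inclusive unless supplied).
#'
#' @param map a \code{\link{stat_map}}.
#' @param path NIfTI file path (.nii or .nii.gz).
#' @param kind map kind tag for the rebuilt map.
#' @param mask optional logical array for the rebuilt grid.
#' @return \code{write_stat_map}: \code{path}, invisibly.
#'   \code{read_stat_map}: a \code{stat_map}.
#' @export
write_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  img <- RNifti::`sform<-`(img, structure(map$grid$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path, kind = "ALE", mask = NULL) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  dims <- dim(img)
  vs <- abs(aff[1, 1])
  grid <- structure(list(dim = as.integer(dims),
                         affine = structure(unclass(aff))[1:4, 1:4],
                         voxel_size = vs,
                         mask = if (is.null(mask)) array(TRUE, dims) else mask),
                    class = "volume_grid")
  dimnames(grid$affine) <- NULL
  attributes(grid$affine) <- list(dim = c(4L, 4L))
  stat_map(grid, array(as.numeric(img), dims), kind = kind)
}
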