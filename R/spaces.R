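## Piecewise-linear MNI <-> Talairach mapping ("Brett" transform).
## Two pure linear maps (no translation), one for z >= 0 (superior to the
## AC-PC plane) and one for z < 0; the origin is a fixed point of both.

.mni2tal_up <- matrix(c(0.9900, 0,       0,
                        0,      0.9688,  0.0460,
                        0,     -0.0485,  0.9189), 3, 3, byrow = TRUE)
.mni2tal_dn <- matrix(c(0.9900, 0,       0,
                        0,      0.9688,  0.0420,
                        0,     -0.0485,  0.8390), 3, 3, byrow = TRUE)
.tal2mni_up <- solve(.mni2tal_up)
.tal2mni_dn <- solve(.mni2tal_dn)

.as_coord_matrix <- function(coord) {
  if (is.null(dim(coord))) coord <- matrix(coord, ncol = 3, byrow = TRUE)
  coord <- as.matrix(coord)
  if (ncol(coord) != 3) stop("coordinates must be 3-vectors (x, y, z)")
  storage.mode(coord) <- "double"
  if (any(!is.finite(coord))) stop("non-finite coordinate")
  coord
}

#' Convert MNI coordinates to Talairach
#'
#' Applies the standard piecewise-linear transform: one linear map for
#' MNI z >= 0 and another for z < 0, no translation term.
#'
#' @param coord a length-3 vector or an n x 3 matrix of MNI mm coordinates.
#' @return Coordinates in Talairach space, same shape as the input.
#' @seealso \code{\link{tal2mni}}
#' @export
mni2tal <- function(coord) {
  v <- .as_coord_matrix(coord)
  up <- v[, 3] >= 0
  out <- v
  if (any(up))  out[up, ]  <- v[up, , drop = FALSE] %*% t(.mni2tal_up)
  if (any(!up)) out[!up, ] <- v[!up, , drop = FALSE] %*% t(.mni2tal_dn)
  if (is.null(dim(coord)) && length(coord) == 3) drop(out) else out
}

#' Convert Talairach coordinates to MNI
#'
#' Exact inverse of \code{\link{mni2tal}}. The half-space is selected by the
#' sign of the OUTPUT (MNI) z: the superior inverse is tried first and the
#' inferior inverse is used when that lands below the axial plane. Because the
#' two forward maps agree in sign of the reconstructed z (the superior inverse
#' applied to an inferior-map image still has negative z), the round trip
#' \code{tal2mni(mni2tal(v))} reproduces \code{v} to machine precision
#' everywhere; z = 0 resolves to the superior map on both legs.
#'
#' @param coord a length-3 vector or an n x 3 matrix of Talairach mm
#'   coordinates.
#' @return Coordinates in MNI space, same shape as the input.
#' @export
tal2mni <- function(coord) {
  t_ <- .as_coord_matrix(coord)
  out <- t_ %*% t(.tal2mni_up)
  low <- out[, 3] < 0
  if (any(low)) out[low, ] <- t_[low, , drop = FALSE] %*% t(.tal2mni_dn)
  if (is.null(dim(coord)) && length(coord) == 3) drop(out) else out
}
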