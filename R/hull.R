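#' 3D convex hull of a point set
#'
#' Incremental convex hull in three dimensions: volume, triangular facets
#' and the outward half-space representation used for membership tests.
#'
#' @param points n x 3 matrix (n >= 4).
#' @return A list with `volume` (mm^3 for mm inputs), `degenerate` (logical;
#'   coplanar or lower-dimensional input gives volume 0 with a warning),
#'   and for proper hulls `faces` (m x 3, 1-based vertex indices),
#'   `normals`, `offsets`.
#' @export
convex_hull_3d <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("convex hull needs at least 4 points")
  res <- cpp_convhull(points)
  if (isTRUE(res$degenerate)) {
    warning("degenerate point set: hull volume is 0")
    return(list(volume = 0, degenerate = TRUE))
  }
  list(volume = res$volume, degenerate = FALSE, faces = res$faces,
       normals = res$normals, offsets = as.numeric(res$offsets))
}

#' Convex hull volume
#'
#' @param points n x 3 matrix (n >= 4).
#' @return Volume (0, with a warning, for degenerate sets).
#' @export
convex_hull_volume <- function(points) {
  convex_hull_3d(points)$volume
}

#' Test points for hull membership
#'
#' @param hull result of [convex_hull_3d()] (non-degenerate).
#' @param points m x 3 matrix.
#' @param tol slack on the face half-spaces (mm).
#' @return Logical vector: inside (or on) the hull.
#' @export
hull_contains <- function(hull, points, tol = 1e-7) {
  stopifnot(!isTRUE(hull$degenerate))
  points <- matrix(as.numeric(points), ncol = 3)
  as.logical(cpp_hull_contains(hull$normals, hull$offsets, points, tol))
}
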