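#' Closest points on a mesh surface
#'
#' Exact point-to-triangle projection of a set of query points onto a mesh
#' (point-to-surface, not point-to-vertex), accelerated by a uniform grid
#' over the mesh vertices.
#'
#' @param mesh a [triangle_mesh()].
#' @param points k x 3 matrix of query points (a single point may be a
#'   length-3 vector).
#' @param boundary precomputed [boundary_vertices()] of `mesh` (saves
#'   recomputation in iterative callers), or `FALSE` to skip boundary
#'   detection entirely.
#' @return list with `points` (k x 3 closest surface points), `dist`
#'   (Euclidean distances, mm), `face` (1-based triangle index), `bary`
#'   (k x 3 barycentric coordinates within that triangle) and `on_boundary`
#'   (logical; TRUE when the match lies on a boundary edge or vertex of an
#'   open mesh; all FALSE when detection is skipped).
#' @export
closest_on_surface <- function(mesh, points, boundary = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  res <- cpp_closest_points(points, mesh$vertices, mesh$faces)
  bv <- if (isFALSE(boundary)) integer(0) else if (is.null(boundary)) {
    boundary_vertices(mesh)
  } else boundary
  if (length(bv) > 0) {
    isb <- logical(nrow(mesh$vertices))
    isb[bv] <- TRUE
    fv <- matrix(isb[mesh$faces[res$face, ]], ncol = 3)
    res$on_boundary <- vapply(seq_len(nrow(points)), function(i) {
      all(fv[i, ][res$bary[i, ] > 1e-8])
    }, logical(1))
  } else {
    res$on_boundary <- rep(FALSE, nrow(points))
  }
  res
}

#' Evaluate barycentric coordinates on a (possibly different) mesh
#'
#' Given triangle indices and barycentric weights obtained on one mesh,
#' evaluates the corresponding points on a mesh sharing the same topology.
#' This is how landmarks travel through dense correspondences.
#'
#' @param mesh a [triangle_mesh()].
#' @param face integer vector of 1-based triangle indices.
#' @param bary k x 3 barycentric weights.
#' @return k x 3 matrix of surface points.
#' @export
barycentric_points <- function(mesh, face, bary) {
  if (is.null(dim(bary))) bary <- matrix(bary, ncol = 3)
  f <- mesh$faces[face, , drop = FALSE]
  v <- mesh$vertices
  v[f[, 1], , drop = FALSE] * bary[, 1] +
    v[f[, 2], , drop = FALSE] * bary[, 2] +
    v[f[, 3], , drop = FALSE] * bary[, 3]
}

#' Nearest mesh vertex per query point (ties: lowest index)
#' @param mesh a [triangle_mesh()].
#' @param points k x 3 matrix (or length-3 vector).
#' @return integer vector of 1-based vertex indices.
#' @export
nearest_vertex <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  as.integer(cpp_nearest_vertex(points, mesh$vertices))
}
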