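#' Construct a triangle mesh
#'
#' The universal surface representation used throughout the package: a set of
#' 3D vertex coordinates (assumed millimetres) and a set of triangular faces
#' indexing into them. Faces are stored 1-based (R convention); file readers
#' and writers convert at the format boundary.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param name label carried through the pipeline (subject id, "template", ...).
#' @param validate check invariants (index range, no degenerate faces).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, name = "", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(
    list(vertices = vertices, faces = faces, name = as.character(name)[1]),
    class = "triangle_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate triangle mesh invariants
#'
#' Checks that the mesh is non-empty, all face indices are in range, no face
#' is degenerate (repeated vertex index), and all coordinates are finite.
#'
#' @param mesh a [triangle_mesh()].
#' @return The mesh, invisibly; stops on violation.
#' @export
validate_mesh <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) stop("not a triangle_mesh")
  nv <- nrow(mesh$vertices)
  if (nv == 0L) stop("mesh has no vertices")
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  f <- mesh$faces
  if (min(f) < 1L || max(f) > nv) stop("face index out of range [1, n_vertices]")
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(degen)) stop(sum(degen), " degenerate face(s) with repeated vertex index")
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "triangle_mesh '%s': %d vertices, %d faces, mean edge %.3f mm\n",
    x$name, nrow(x$vertices), nrow(x$faces), mean_edge_length(x)
  ))
  invisible(x)
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return integer matrix, e x 2, each row an edge with smaller index first.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Mean edge length of a mesh (mm)
#' @param mesh a [triangle_mesh()].
#' @return scalar, mean Euclidean edge length.
#' @export
mean_edge_length <- function(mesh) mean(edge_lengths(mesh))

#' Per-face normals and areas
#' @param mesh a [triangle_mesh()].
#' @return list with `normals` (m x 3 unit rows; zero rows for degenerate
#'   geometry) and `areas` (length m).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  nrm <- sqrt(rowSums(cr * cr))
  n <- cr / ifelse(nrm > 0, nrm, 1)
  n[nrm == 0, ] <- 0
  list(normals = n, areas = nrm / 2)
}

#' Area-weighted per-vertex unit normals
#'
#' Averages incident face normals weighted by face area. Outward-facing for a
#' consistently wound mesh; flipping all face windings negates every normal.
#' Isolated vertices (no incident face) get a zero normal.
#'
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit (or zero) normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  w <- fn$normals * fn$areas
  n <- matrix(0, nrow(mesh$vertices), 3)
  idx <- as.vector(mesh$faces)
  for (j in 1:3) {
    n[, j] <- tapply_add(rep(w[, j], 3L), idx, nrow(n))
  }
  len <- sqrt(rowSums(n * n))
  n / ifelse(len > 0, len, 1)
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Signed volume of a closed mesh (divergence theorem)
#' @param mesh a closed, consistently wound [triangle_mesh()].
#' @return scalar volume in mm^3 (positive for outward winding).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Boundary vertices of a mesh
#'
#' An edge is a boundary edge when it belongs to exactly one face (open
#' meshes arise from field-of-view cropping of clinical scans).
#'
#' @param mesh a [triangle_mesh()].
#' @return integer vector of boundary vertex indices (possibly empty).
#' @export
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(integer(0))
  bd <- do.call(rbind, strsplit(bkey, " ", fixed = TRUE))
  sort(unique(as.integer(bd)))
}

#' Edge-graph of a mesh as an igraph object
#'
#' Vertices are mesh vertices, edges are mesh edges weighted by Euclidean
#' length; used for geodesic (shortest-path) queries.
#'
#' @param mesh a [triangle_mesh()].
#' @return an `igraph` graph with a `weight` edge attribute in mm.
#' @export
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$weight <- edge_lengths(mesh, e)
  g
}

#' Geodesic neighborhood of a vertex
#'
#' All vertices whose shortest-path distance to `center` along the edge graph
#' (Euclidean edge weights) is at most `radius`. This approximates the
#' polyhedral geodesic distance; it is sufficient for gating local extremum
#' searches and is monotone in `radius` by construction.
#'
#' @param mesh a [triangle_mesh()].
#' @param center vertex index (1-based).
#' @param radius search radius in mm, > 0.
#' @param graph optional precomputed [mesh_graph()] (saves rebuilding in loops).
#' @return list of class `vertex_neighborhood` with `center`, `members`
#'   (sorted vertex indices, always containing `center`), `distances`
#'   (named by member index) and `radius`.
#' @export
geodesic_neighborhood <- function(mesh, center, radius, graph = NULL) {
  nv <- nrow(mesh$vertices)
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > nv) {
    stop("center vertex index out of range")
  }
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (is.null(graph)) graph <- mesh_graph(mesh)
  d <- as.vector(igraph::distances(graph, v = center))
  members <- which(d <= radius)
  structure(
    list(center = center, members = members,
         distances = stats::setNames(d[members], members), radius = radius),
    class = "vertex_neighborhood"
  )
}

#' Connected components of a mesh; keep-largest cleanup
#'
#' @param mesh a [triangle_mesh()].
#' @return integer vector of component ids per vertex.
#' @export
mesh_components <- function(mesh) {
  igraph::components(mesh_graph(mesh))$membership
}

#' Drop unused vertices, duplicate faces, and minor components
#'
#' Welds duplicate vertices closer than `weld_tol`, removes degenerate and
#' duplicate faces and unreferenced vertices, and (if the result is still
#' disconnected) keeps only the largest connected component with a warning.
#'
#' @param mesh a [triangle_mesh()] (may violate invariants on input).
#' @param weld_tol vertices closer than this (mm) are merged.
#' @param keep_largest drop all but the largest connected component.
#' @return a cleaned, valid [triangle_mesh()].
#' @export
clean_mesh <- function(mesh, weld_tol = 1e-6, keep_largest = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  if (weld_tol > 0 && nrow(v) > 1) {
    key <- paste(round(v[, 1] / weld_tol), round(v[, 2] / weld_tol),
                 round(v[, 3] / weld_tol))
    first <- match(key, key)
    keep <- which(first == seq_along(first))
    remap <- match(first, keep)
    v <- v[keep, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3)
  }
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  fs <- t(apply(f, 1, sort))
  f <- f[!duplicated(fs), , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)
  out <- triangle_mesh(v, f, name = mesh$name)
  comp <- mesh_components(out)
  if (max(comp) > 1L) {
    if (!keep_largest) stop("mesh has ", max(comp), " connected components")
    warning("mesh has ", max(comp), " components; keeping the largest")
    big <- which.max(tabulate(comp))
    keepv <- which(comp == big)
    keepf <- apply(matrix(out$faces %in% keepv, ncol = 3), 1, all)
    remap <- integer(nrow(out$vertices))
    remap[keepv] <- seq_along(keepv)
    out <- triangle_mesh(out$vertices[keepv, , drop = FALSE],
                         matrix(remap[out$faces[keepf, ]], ncol = 3),
                         name = mesh$name)
  }
  out
}

#' Apply a function to mesh vertices, preserving topology
#' @param mesh a [triangle_mesh()].
#' @param fn function taking and returning an n x 3 matrix.
#' @return transformed mesh.
#' @export
map_vertices <- function(mesh, fn) {
  triangle_mesh(fn(mesh$vertices), mesh$faces, name = mesh$name,
                validate = FALSE)
}
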