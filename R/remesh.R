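#' Isotropic remeshing
#'
#' Drives the edge-length distribution of a mesh toward a uniform target by
#' the classical cycle of operations per iteration: split edges longer than
#' 4/3 of the target, collapse edges shorter than 4/5 of the target, flip
#' edges toward regular vertex valence, and tangentially smooth with
#' back-projection onto the original surface. The result approximates the
#' input surface (deviation is bounded by the back-projection) but makes no
#' guarantee about the exact vertex count.
#'
#' Boundary edges of open meshes are split but never collapsed or flipped,
#' and boundary vertices are not smoothed, so cropped field-of-view rims
#' keep their shape.
#'
#' @param mesh a [triangle_mesh()].
#' @param target_edge_length desired edge length in mm, > 0.
#' @param iterations number of split/collapse/flip/smooth cycles.
#' @return remeshed [triangle_mesh()].
#' @export
isotropic_remesh <- function(mesh, target_edge_length, iterations = 5) {
  validate_mesh(mesh)
  if (!is.numeric(target_edge_length) || target_edge_length <= 0) {
    stop("target_edge_length must be > 0")
  }
  L <- target_edge_length
  diag_len <- sqrt(sum((apply(mesh$vertices, 2, max) -
                          apply(mesh$vertices, 2, min))^2))
  if (L > diag_len / 2) {
    stop("target edge length too coarse: mesh would degenerate")
  }
  ref <- mesh  # original surface for back-projection
  V <- mesh$vertices
  F <- mesh$faces
  for (it in seq_len(iterations)) {
    sp <- remesh_split(V, F, 4 / 3 * L)
    V <- sp$V; F <- sp$F
    co <- remesh_collapse(V, F, 4 / 5 * L, 4 / 3 * L)
    V <- co$V; F <- co$F
    if (nrow(F) < 4L) stop("target edge length too coarse: mesh degenerated")
    F <- remesh_flip(V, F)
    V <- remesh_smooth(V, F, ref)
  }
  out <- clean_mesh(triangle_mesh(V, F, name = mesh$name, validate = FALSE))
  validate_mesh(out)
  out
}

# split every edge longer than lmax at its midpoint
remesh_split <- function(V, F, lmax) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  len <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
  long <- e[len > lmax, , drop = FALSE]
  if (nrow(long) == 0L) return(list(V = V, F = F))
  mid <- (V[long[, 1], , drop = FALSE] + V[long[, 2], , drop = FALSE]) / 2
  newid <- nrow(V) + seq_len(nrow(long))
  V <- rbind(V, mid)
  splitmap <- new.env(hash = TRUE)
  for (i in seq_len(nrow(long))) {
    assign(paste(long[i, 1], long[i, 2]), newid[i], envir = splitmap)
  }
  getmid <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    if (exists(k, envir = splitmap, inherits = FALSE)) {
      get(k, envir = splitmap, inherits = FALSE)
    } else NA_integer_
  }
  out <- vector("list", nrow(F))
  for (i in seq_len(nrow(F))) {
    a <- F[i, 1]; b <- F[i, 2]; c3 <- F[i, 3]
    m <- c(getmid(a, b), getmid(b, c3), getmid(c3, a))
    ns <- sum(!is.na(m))
    if (ns == 0L) {
      out[[i]] <- matrix(c(a, b, c3), 1)
    } else if (ns == 3L) {
      out[[i]] <- rbind(c(a, m[1], m[3]), c(m[1], b, m[2]),
                        c(m[3], m[2], c3), c(m[1], m[2], m[3]))
    } else {
      # rotate so the first edge is split
      vs <- c(a, b, c3)
      while (is.na(m[1])) {
        vs <- vs[c(2, 3, 1)]
        m <- m[c(2, 3, 1)]
      }
      a <- vs[1]; b <- vs[2]; c3 <- vs[3]
      if (ns == 1L) {
        out[[i]] <- rbind(c(a, m[1], c3), c(m[1], b, c3))
      } else if (is.na(m[2])) { # edges 1 and 3 split
        out[[i]] <- rbind(c(a, m[1], m[3]), c(m[1], b, c3), c(m[3], m[1], c3))
      } else {                  # edges 1 and 2 split
        out[[i]] <- rbind(c(a, m[1], c3), c(m[1], b, m[2]), c(m[1], m[2], c3))
      }
    }
  }
  list(V = V, F = do.call(rbind, out))
}

vertex_adjacency <- function(F, nv) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)],
             F[, c(2, 1)], F[, c(3, 2)], F[, c(1, 3)])
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(nv)))
  lapply(adj, function(x) sort(unique(x)))
}

boundary_flags <- function(F, nv) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  flags <- logical(nv)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey)) {
    bd <- as.integer(unlist(strsplit(bkey, " ", fixed = TRUE)))
    flags[bd] <- TRUE
  }
  flags
}

# greedy collapse of edges shorter than lmin into their midpoint
remesh_collapse <- function(V, F, lmin, lmax) {
  nv <- nrow(V)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  len <- sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2))
  ord <- order(len)
  short <- ord[len[ord] < lmin]
  if (length(short) == 0L) return(list(V = V, F = F))
  adj <- vertex_adjacency(F, nv)
  onb <- boundary_flags(F, nv)
  locked <- logical(nv)
  remap <- seq_len(nv)
  for (k in short) {
    u <- e[k, 1]; v <- e[k, 2]
    if (locked[u] || locked[v] || onb[u] || onb[v]) next
    common <- intersect(adj[[u]], adj[[v]])
    if (length(common) != 2L) next  # link condition (interior edge)
    mid <- (V[u, ] + V[v, ]) / 2
    # reject collapses that would create over-long edges
    nb <- setdiff(union(adj[[u]], adj[[v]]), c(u, v))
    dn <- sqrt(rowSums((V[nb, , drop = FALSE] -
                          matrix(mid, length(nb), 3, byrow = TRUE))^2))
    if (any(dn > lmax)) next
    V[u, ] <- mid
    remap[v] <- u
    locked[c(u, v, nb)] <- TRUE
  }
  F2 <- matrix(remap[F], ncol = 3)
  degen <- F2[, 1] == F2[, 2] | F2[, 2] == F2[, 3] | F2[, 1] == F2[, 3]
  F2 <- F2[!degen, , drop = FALSE]
  fs <- t(apply(F2, 1, sort))
  F2 <- F2[!duplicated(fs), , drop = FALSE]
  used <- sort(unique(as.vector(F2)))
  remap2 <- integer(nrow(V))
  remap2[used] <- seq_along(used)
  list(V = V[used, , drop = FALSE], F = matrix(remap2[F2], ncol = 3))
}

# flip interior edges when the summed squared valence deviation improves
remesh_flip <- function(V, F) {
  nv <- nrow(V)
  # edge -> adjacent faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fidx <- rep(seq_len(nrow(F)), 3L)
  byedge <- split(fidx, key)
  onb <- boundary_flags(F, nv)
  val <- tabulate(as.vector(F), nbins = nv) # approx valence via face corners
  # valence = number of distinct neighbors; corner count equals it for
  # interior manifold vertices and valence-1... use adjacency for accuracy
  adj <- vertex_adjacency(F, nv)
  val <- lengths(adj)
  target <- ifelse(onb, 4L, 6L)
  edges_exist <- new.env(hash = TRUE)
  for (k in names(byedge)) assign(k, TRUE, envir = edges_exist)
  dirty <- logical(nrow(F))
  for (k in names(byedge)) {
    fs <- byedge[[k]]
    if (length(fs) != 2L || any(dirty[fs])) next
    uv <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    u <- uv[1]; v <- uv[2]
    t1 <- F[fs[1], ]; t2 <- F[fs[2], ]
    c1 <- setdiff(t1, uv); c2 <- setdiff(t2, uv)
    if (length(c1) != 1L || length(c2) != 1L || c1 == c2) next
    nk <- paste(min(c1, c2), max(c1, c2))
    if (exists(nk, envir = edges_exist, inherits = FALSE)) next
    dev <- function(vi, delta) (val[vi] + delta - target[vi])^2
    before <- dev(u, 0) + dev(v, 0) + dev(c1, 0) + dev(c2, 0)
    after <- dev(u, -1) + dev(v, -1) + dev(c1, 1) + dev(c2, 1)
    if (after >= before) next
    # geometric sanity: keep orientation consistent with t1's winding
    ord1 <- orient_pair(t1, u, v)
    F[fs[1], ] <- c(ord1[1], c2, c1)
    F[fs[2], ] <- c(ord1[2], c1, c2)
    val[u] <- val[u] - 1L; val[v] <- val[v] - 1L
    val[c1] <- val[c1] + 1L; val[c2] <- val[c2] + 1L
    assign(nk, TRUE, envir = edges_exist)
    dirty[fs] <- TRUE
  }
  F
}

# return (u, v) ordered as they appear cyclically in triangle t
orient_pair <- function(t, u, v) {
  iu <- which(t == u)
  nxt <- t[c(2, 3, 1)][iu]
  if (nxt == v) c(u, v) else c(v, u)
}

# tangential Laplacian smoothing + back-projection to the reference surface
remesh_smooth <- function(V, F, ref, lambda = 0.6) {
  nv <- nrow(V)
  adj <- vertex_adjacency(F, nv)
  onb <- boundary_flags(F, nv)
  m <- triangle_mesh(V, F, validate = FALSE)
  n <- vertex_normals(m)
  Vnew <- V
  for (i in seq_len(nv)) {
    if (onb[i] || length(adj[[i]]) == 0L) next
    g <- colMeans(V[adj[[i]], , drop = FALSE])
    d <- g - V[i, ]
    d <- d - sum(d * n[i, ]) * n[i, ]
    Vnew[i, ] <- V[i, ] + lambda * d
  }
  proj <- closest_on_surface(ref, Vnew)
  Vout <- proj$points
  Vout[onb, ] <- Vnew[onb, ]  # keep rim where it is
  Vout
}
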