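# Small programmatic fixtures and independent oracles shared across tests.

tetra_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
    name = "tetra"
  )
}

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # z = 0
    c(5, 6, 7), c(6, 8, 7),    # z = 1
    c(1, 2, 5), c(2, 6, 5),    # y = 0
    c(3, 7, 4), c(4, 7, 8),    # y = 1
    c(1, 5, 3), c(3, 5, 7),    # x = 0
    c(2, 4, 6), c(4, 8, 6)     # x = 1
  )
  triangle_mesh(v, f, name = "cube")
}

# independent geodesic oracle: plain Dijkstra over the edge graph with an
# early radius cut-off (no igraph). Adjacency can be precomputed with
# oracle_adjacency() when many queries hit the same mesh.
oracle_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  nv <- nrow(mesh$vertices)
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  w <- c(len, len)
  f <- factor(from, levels = seq_len(nv))
  list(nb = split(to, f), w = split(w, f), nv = nv)
}

oracle_geodesic <- function(mesh, center, radius, adj = NULL) {
  if (is.null(adj)) adj <- oracle_adjacency(mesh)
  dist <- rep(Inf, adj$nv)
  done <- logical(adj$nv)
  dist[center] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    u <- cand[which.min(dist[cand])]
    if (dist[u] > radius) break
    done[u] <- TRUE
    nb <- adj$nb[[u]]
    if (length(nb)) {
      nd <- dist[u] + adj$w[[u]]
      upd <- nd < dist[nb]
      dist[nb[upd]] <- nd[upd]
    }
  }
  dist
}

# independent extremum oracle: exhaustive scan of the geodesic neighborhood
oracle_extremum <- function(mesh, seed_vertex, definition, frame, radius,
                            adj = NULL) {
  d <- oracle_geodesic(mesh, seed_vertex, radius, adj = adj)
  members <- which(d <= radius)
  coords <- to_frame(mesh$vertices, frame)
  ax <- match(definition$refine_axis, c("x", "y", "z"))
  val <- coords[members, ax]
  if (definition$refine_sense == "min") val <- -val
  top <- members[val == max(val)]
  if (length(top) > 1L && !is.na(definition$secondary_axis) &&
      definition$secondary_axis != "none") {
    sv <- coords[top, match(definition$secondary_axis, c("x", "y", "z"))]
    if (definition$secondary_sense == "min") sv <- -sv
    top <- top[sv == max(sv)]
  }
  min(top)
}

# the end-to-end rehearsal is expensive; compute it once per test run
rehearsal_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- phantom_rehearsal(n_subjects = 6, magnitude = 2,
                                  smoothness = 20, seed = 42)
    }
    cache
  }
})

random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

# random complete subjects x raters table with known variance components
random_rater_table <- function(n, k, sd_subject = 2, sd_rater = 0.7,
                               sd_error = 0.7) {
  outer(rnorm(n, sd = sd_subject), rep(1, k)) +
    outer(rep(1, n), rnorm(k, sd = sd_rater)) +
    matrix(rnorm(n * k, sd = sd_error), n, k)
}

# ICC(A,1) oracle via stats::aov mean squares (independent of the package's
# own closed-form decomposition)
oracle_icc_a1 <- function(tab) {
  n <- nrow(tab)
  k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
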