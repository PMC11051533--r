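#' Registration configuration
#'
#' Parameters controlling rigid alignment and constrained elastic
#' deformation of a template onto a target.
#'
#' @param max_rigid_iters maximum ICP iterations for rigid alignment.
#' @param elastic_steps number of outer stiffness relaxation steps.
#' @param stiffness_schedule strictly decreasing positive smoothness weights,
#'   one per outer step; default halves from 100 down to ~0.8.
#' @param normal_compat_threshold maximum angle (degrees) between the
#'   deforming template vertex normal and the matched target surface normal
#'   for a correspondence to be accepted.
#' @param max_corr_distance maximum point-to-surface distance (mm) for a
#'   correspondence to be accepted.
#' @param convergence_tol stop when the maximum vertex displacement of an
#'   iteration falls below this (mm).
#' @param inner_iters correspondence/solve sweeps per stiffness step.
#' @return list of class `registration_config`.
#' @export
registration_config <- function(max_rigid_iters = 50,
                                elastic_steps = 8,
                                stiffness_schedule = 100 * 0.5^(0:7),
                                normal_compat_threshold = 60,
                                max_corr_distance = 10,
                                convergence_tol = 0.01,
                                inner_iters = 3) {
  if (length(stiffness_schedule) != elastic_steps) {
    stiffness_schedule <- 100 * 0.5^(seq_len(elastic_steps) - 1)
  }
  if (any(stiffness_schedule <= 0) || any(diff(stiffness_schedule) >= 0)) {
    stop("stiffness_schedule must be strictly decreasing and positive")
  }
  structure(list(
    max_rigid_iters = max_rigid_iters,
    elastic_steps = elastic_steps,
    stiffness_schedule = stiffness_schedule,
    normal_compat_threshold = normal_compat_threshold,
    max_corr_distance = max_corr_distance,
    convergence_tol = convergence_tol,
    inner_iters = inner_iters
  ), class = "registration_config")
}

#' Rigid transform (rotation + translation, optional uniform scale)
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param translation length-3 vector (mm).
#' @param scale positive scalar, default 1.
#' @return list of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  if (scale <= 0) stop("scale must be positive")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale), class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#' @param transform a [rigid_transform()].
#' @param x n x 3 matrix, length-3 vector, or [triangle_mesh()].
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(transform, x) {
  tf <- function(p) {
    drop1 <- is.null(dim(p))
    if (drop1) p <- matrix(p, ncol = 3)
    out <- transform$scale * p %*% t(transform$rotation) +
      matrix(transform$translation, nrow(p), 3, byrow = TRUE)
    if (drop1) drop(out) else out
  }
  if (inherits(x, "triangle_mesh")) map_vertices(x, tf) else tf(x)
}

#' Compose two rigid transforms (b after a)
#' @param a,b [rigid_transform()] objects; result applies `a` first.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  b$scale * as.vector(b$rotation %*% a$translation) +
                    b$translation,
                  scale = a$scale * b$scale)
}

# Kabsch/Umeyama best-fit rigid transform mapping P onto Q (row-paired)
fit_rigid <- function(P, Q, weights = NULL, allow_scale = FALSE) {
  if (is.null(weights)) weights <- rep(1, nrow(P))
  w <- weights / sum(weights)
  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc * w, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  s <- if (allow_scale) {
    sum(diag(S) * sv$d) / sum(w * rowSums(Pc^2))
  } else 1
  t <- cq - s * as.vector(R %*% cp)
  rigid_transform(R, t, scale = s)
}

#' Rigid ICP alignment of a source mesh onto a target mesh
#'
#' Iterative closest point with point-to-surface correspondences: each
#' iteration matches every source vertex to its closest point on the target
#' surface (correspondences farther than `max_corr_distance` rejected) and
#' solves the best-fit rigid transform in closed form. The mean squared
#' correspondence distance is non-increasing over iterations; iteration
#' stops at `convergence_tol` (change in RMS, mm) or `max_rigid_iters`.
#' Centroids are pre-aligned first.
#'
#' @param source,target [triangle_mesh()] objects.
#' @param config a [registration_config()].
#' @param allow_scale estimate a uniform scale factor as well.
#' @return a [rigid_transform()] mapping source coordinates onto the target,
#'   with attributes `rms` (final RMS correspondence distance) and
#'   `iterations`.
#' @export
rigid_align <- function(source, target, config = registration_config(),
                        allow_scale = FALSE) {
  validate_mesh(source)
  validate_mesh(target)
  P0 <- source$vertices
  tf <- rigid_transform(diag(3), colMeans(target$vertices) - colMeans(P0))
  rms_prev <- Inf
  iters <- 0L
  for (it in seq_len(config$max_rigid_iters)) {
    P <- apply_transform(tf, P0)
    cp <- closest_on_surface(target, P, boundary = FALSE)
    keep <- cp$dist <= config$max_corr_distance
    if (sum(keep) < 3L) {
      stop("no correspondences within max_corr_distance; pre-align the meshes")
    }
    step <- fit_rigid(P[keep, , drop = FALSE], cp$points[keep, , drop = FALSE],
                      allow_scale = allow_scale)
    tf <- compose_transform(step, tf)
    P <- apply_transform(tf, P0)
    cp <- closest_on_surface(target, P, boundary = FALSE)
    rms <- sqrt(mean(pmin(cp$dist, config$max_corr_distance)^2))
    iters <- it
    if (rms < 1e-12 || abs(rms_prev - rms) < config$convergence_tol * 1e-3) break
    rms_prev <- rms
  }
  # point-to-plane polish: projection-based ICP can stall with purely
  # tangential residuals; a few Gauss-Newton steps on the linearized
  # point-to-plane objective remove that bias
  fn <- face_normals(target)$normals
  for (it in seq_len(20)) {
    P <- apply_transform(tf, P0)
    cp <- closest_on_surface(target, P, boundary = FALSE)
    keep <- cp$dist <= config$max_corr_distance
    if (sum(keep) < 6L) break
    p <- P[keep, , drop = FALSE]
    n <- fn[cp$face[keep], , drop = FALSE]
    r <- rowSums((p - cp$points[keep, , drop = FALSE]) * n)
    J <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
               p[, 3] * n[, 1] - p[, 1] * n[, 3],
               p[, 1] * n[, 2] - p[, 2] * n[, 1],
               n)
    x <- tryCatch(solve(crossprod(J), -crossprod(J, r)), error = function(e) NULL)
    if (is.null(x)) break
    ang <- sqrt(sum(x[1:3]^2))
    Rs <- if (ang < 1e-15) diag(3) else {
      ax <- x[1:3] / ang
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                  3, 3)
      diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    }
    tf <- compose_transform(rigid_transform(Rs, x[4:6]), tf)
    if (ang < 1e-10 && max(abs(x[4:6])) < 1e-10) break
  }
  P <- apply_transform(tf, P0)
  cp <- closest_on_surface(target, P, boundary = FALSE)
  rms <- sqrt(mean(pmin(cp$dist, config$max_corr_distance)^2))
  attr(tf, "rms") <- rms
  attr(tf, "iterations") <- iters
  tf
}

#' Elastic registration: impose template topology on a target surface
#'
#' Rigidly pre-aligns the template (via [rigid_align()]), then progressively
#' deforms it into the target under a graph-Laplacian stiffness prior on the
#' per-vertex displacement field. At each stiffness level the algorithm
#' alternates (a) matching every template vertex to its closest compatible
#' point on the target surface -- a match is rejected when it is farther than
#' `max_corr_distance`, when the target surface normal deviates from the
#' template vertex normal by more than `normal_compat_threshold` degrees, or
#' when it falls on the boundary rim of an open target -- and (b) solving the
#' sparse linear system minimizing
#' \deqn{\sum_i w_i \|v_i + d_i - c_i\|^2 +
#'       \alpha \sum_{(i,j) \in E} \|d_i - d_j\|^2}
#' for the displacement field d. The stiffness alpha is relaxed along
#' `stiffness_schedule`, so large-scale alignment happens first and local
#' detail is matched last.
#'
#' A symmetric data term (weight `reverse_weight`) additionally matches
#' every target vertex to its closest point on the deforming template and
#' pulls the template triangle's barycentric footprint toward it; this
#' counteracts tangential sliding of the correspondence over nearly flat or
#' gently curved regions, which a one-way closest-point term cannot observe.
#'
#' @param template,target [triangle_mesh()] objects.
#' @param config a [registration_config()].
#' @param rigid perform rigid pre-alignment (disable when the meshes are
#'   already in a common pose).
#' @param reverse_weight relative weight of the symmetric (target-to-
#'   template) data term; 0 disables it.
#' @return a `corresponded_mesh`: the deformed template (same topology) with
#'   fields `vertices`, `faces`, `residual` (per-vertex distance to the
#'   target surface), `source_target` (target name) and `template_name`.
#'   Warns when fewer than 95% of vertices end up within
#'   `max_corr_distance` of the target.
#' @export
elastic_register <- function(template, target, config = registration_config(),
                             rigid = TRUE, reverse_weight = 1) {
  validate_mesh(template)
  validate_mesh(target)
  V0 <- template$vertices
  if (rigid) {
    tf <- rigid_align(template, target, config)
    V0 <- apply_transform(tf, V0)
  }
  nv <- nrow(V0)
  edges <- mesh_edges(template)
  ii <- c(edges[, 1], edges[, 2])
  jj <- c(edges[, 2], edges[, 1])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nv, nv))
  Lap <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  cosmax <- cos(config$normal_compat_threshold * pi / 180)
  tmpl_boundary <- boundary_flags(template$faces, nv)
  tgt_fnorm <- face_normals(target)$normals
  tgt_boundary <- boundary_vertices(target)
  tgt_is_boundary <- logical(nrow(target$vertices))
  tgt_is_boundary[tgt_boundary] <- TRUE
  X <- V0
  D <- matrix(0, nv, 3)
  trace <- list()
  for (alpha in config$stiffness_schedule) {
    for (inner in seq_len(config$inner_iters)) {
      tn <- vertex_normals(triangle_mesh(X, template$faces, validate = FALSE))
      cp <- closest_on_surface(target, X, boundary = tgt_boundary)
      w <- as.numeric(cp$dist <= config$max_corr_distance)
      ndot <- rowSums(tn * tgt_fnorm[cp$face, , drop = FALSE])
      w[ndot < cosmax] <- 0
      w[cp$on_boundary & tmpl_boundary] <- 0
      if (sum(w) < 10) {
        stop("surfaces do not overlap: almost no valid correspondences")
      }
      M <- Matrix::Diagonal(x = w) + alpha * Lap
      rhs <- w * (cp$points - V0)
      Arev <- NULL
      if (reverse_weight > 0) {
        cur <- triangle_mesh(X, template$faces, validate = FALSE)
        rp <- closest_on_surface(cur, target$vertices, boundary = FALSE)
        wr <- as.numeric(rp$dist <= config$max_corr_distance) * reverse_weight
        wr[tgt_is_boundary] <- 0
        fidx <- template$faces[rp$face, , drop = FALSE]
        Arev <- Matrix::sparseMatrix(
          i = rep(seq_len(nrow(fidx)), 3L),
          j = as.vector(fidx),
          x = as.vector(rp$bary),
          dims = c(nrow(fidx), nv))
        M <- M + Matrix::crossprod(Arev * sqrt(wr))
        rhs <- rhs + as.matrix(Matrix::crossprod(
          Arev, wr * (target$vertices - as.matrix(Arev %*% V0))))
      }
      Dnew <- as.matrix(Matrix::solve(M, rhs))
      move <- sqrt(max(rowSums((Dnew - D)^2)))
      D <- Dnew
      X <- V0 + D
      obj <- sum(w * rowSums((X - cp$points)^2)) +
        alpha * sum((D[edges[, 1], ] - D[edges[, 2], ])^2)
      if (!is.null(Arev)) {
        rres <- as.matrix(Arev %*% X) - target$vertices
        obj <- obj + sum(wr * rowSums(rres^2))
      }
      trace[[length(trace) + 1L]] <- c(alpha = alpha, objective = obj)
      if (move < config$convergence_tol) break
    }
  }
  res <- closest_on_surface(target, X, boundary = FALSE)
  frac <- mean(res$dist <= config$max_corr_distance)
  if (frac < 0.95) {
    warning(sprintf(
      "elastic registration onto '%s' incomplete: %.1f%% of vertices within %g mm",
      target$name, 100 * frac, config$max_corr_distance))
  }
  out <- structure(
    list(vertices = X, faces = template$faces, name = target$name,
         residual = res$dist, source_target = target$name,
         template_name = template$name),
    class = c("corresponded_mesh", "triangle_mesh")
  )
  attr(out, "objective_trace") <- do.call(rbind, trace)
  out
}

#' Treat an existing mesh as its own corresponded version
#'
#' Utility for feeding a template/mean shape into operations that expect the
#' shared-topology `corresponded_mesh` contract (identity correspondence,
#' zero residual).
#'
#' @param mesh a [triangle_mesh()].
#' @return a `corresponded_mesh`.
#' @export
as_corresponded <- function(mesh) {
  structure(
    list(vertices = mesh$vertices, faces = mesh$faces, name = mesh$name,
         residual = rep(0, nrow(mesh$vertices)),
         source_target = mesh$name, template_name = mesh$name),
    class = c("corresponded_mesh", "triangle_mesh")
  )
}

#' Vertex-wise mean shape of corresponded meshes
#'
#' All inputs must share the template topology (same vertex count and face
#' list); the mean shape averages corresponding vertex coordinates.
#'
#' @param corresponded list of `corresponded_mesh` / [triangle_mesh()]
#'   objects with identical topology.
#' @param name label for the output mesh.
#' @return a [triangle_mesh()].
#' @export
mean_shape <- function(corresponded, name = "mean_shape") {
  if (length(corresponded) == 0L) stop("no meshes given")
  f0 <- corresponded[[1]]$faces
  n0 <- nrow(corresponded[[1]]$vertices)
  acc <- matrix(0, n0, 3)
  for (m in corresponded) {
    if (nrow(m$vertices) != n0 || !identical(m$faces, f0)) {
      stop("topology mismatch: meshes do not share the template topology")
    }
    acc <- acc + m$vertices
  }
  triangle_mesh(acc / length(corresponded), f0, name = name)
}

#' Triangle distortion of a deformed mesh relative to its template
#'
#' For each triangle, the 2D affine map taking the template triangle to the
#' deformed triangle (in their own planes) is computed; the reported quality
#' metric is its condition number (ratio of singular values), which is >= 1
#' and equals 1 exactly when the triangle is preserved up to a similarity
#' (rotation + uniform scale). Degenerate deformed triangles get Inf.
#'
#' @param deformed a `corresponded_mesh` (or mesh with identical topology).
#' @param template the template [triangle_mesh()].
#' @param threshold triangles with metric above this are flagged.
#' @return list of class `distortion_report` with `metric` (per triangle),
#'   `flagged_triangles` (indices above threshold) and `threshold`.
#' @export
triangle_distortion <- function(deformed, template, threshold = 5) {
  if (!identical(deformed$faces, template$faces)) {
    stop("topology mismatch between deformed mesh and template")
  }
  f <- template$faces
  tri2d <- function(V) {
    e1 <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
    e2 <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
    a <- sqrt(rowSums(e1^2))
    b <- rowSums(e1 * e2) / ifelse(a > 0, a, 1)
    h2 <- rowSums(e2^2) - b^2
    h <- sqrt(pmax(h2, 0))
    list(a = a, b = b, h = h)  # edge1 = (a,0), edge2 = (b,h)
  }
  t1 <- tri2d(template$vertices)
  t2 <- tri2d(deformed$vertices)
  m <- nrow(f)
  metric <- numeric(m)
  for (i in seq_len(m)) {
    T1 <- matrix(c(t1$a[i], 0, t1$b[i], t1$h[i]), 2, 2)
    T2 <- matrix(c(t2$a[i], 0, t2$b[i], t2$h[i]), 2, 2)
    if (abs(det(T1)) < 1e-12) {
      metric[i] <- Inf
      next
    }
    Mmap <- T2 %*% solve(T1)
    s <- svd(Mmap)$d
    metric[i] <- if (s[2] < 1e-12) Inf else s[1] / s[2]
  }
  structure(list(metric = metric,
                 flagged_triangles = which(metric > threshold),
                 threshold = threshold),
            class = "distortion_report")
}
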