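# Synthetic condyle phantoms: stylized distal-femur / proximal-tibia surfaces
# built from a base ellipsoid plus smooth radial Gaussian bumps, with
# analytic (continuous-surface) ground-truth landmarks. They stand in for
# clinical meshes so that registration, propagation, refinement, measurement
# and the agreement statistics can all be validated without any scan data.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Icosphere (subdivided icosahedron) unit-sphere mesh
#' @param subdivisions number of 1-to-4 triangle subdivision rounds.
#' @param radius sphere radius.
#' @return a [triangle_mesh()] with 10 * 4^subdivisions + 2 vertices.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (exists(k, envir = midcache, inherits = FALSE)) {
        return(get(k, envir = midcache, inherits = FALSE))
      }
      m <- (v[a, ] + v[b, ])
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      assign(k, id, envir = midcache)
      id
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c3); ca <- getmid(c3, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c3, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  triangle_mesh(v * radius, f, name = "icosphere")
}

#' Phantom specification
#'
#' The phantom coordinate convention is the canonical reference frame of a
#' right knee: +x lateral, +y anterior, +z proximal; units mm at scale 1.
#'
#' @param bone "femur_like" or "tibia_like".
#' @param scale global size factor (1 = typical adult knee).
#' @param condyle_offsets list with `medial` and `lateral` length-3 vectors
#'   (mm) displacing the posterior condyle lobes, for controlled shape
#'   perturbation.
#' @param bump_scale multiplies all lobe amplitudes.
#' @param mesh_resolution target edge length in mm; must resolve the
#'   narrowest lobe (error if edge length would exceed half the lobe width).
#' @param seed RNG seed (generation itself is deterministic; the seed feeds
#'   derived randomness such as observer simulation defaults).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(bone = c("femur_like", "tibia_like"), scale = 1,
                         condyle_offsets = NULL, bump_scale = 1,
                         mesh_resolution = 2.5, seed = 1L) {
  bone <- match.arg(bone)
  if (mesh_resolution <= 0) stop("mesh_resolution must be > 0")
  if (bump_scale < 0) stop("bump_scale must be >= 0")
  if (is.null(condyle_offsets)) {
    condyle_offsets <- list(medial = c(0, 0, 0), lateral = c(0, 0, 0))
  }
  structure(list(bone = bone, scale = scale,
                 condyle_offsets = condyle_offsets, bump_scale = bump_scale,
                 mesh_resolution = mesh_resolution, seed = as.integer(seed)),
            class = "phantom_spec")
}

# lobe tables: direction (unnormalized, canonical frame), amplitude mm,
# angular width rad. Negative amplitude carves (the intercondylar notch).
femur_lobes <- function() {
  rbind(
    data.frame(name = "post_med", dx = -0.55, dy = -1.00, dz = -0.32, A = 12, w = 0.22),
    data.frame(name = "post_lat", dx = 0.55, dy = -1.00, dz = -0.32, A = 12, w = 0.22),
    data.frame(name = "dist_med", dx = -0.55, dy = -0.18, dz = -1.00, A = 12, w = 0.22),
    data.frame(name = "dist_lat", dx = 0.55, dy = -0.18, dz = -1.00, A = 12, w = 0.22),
    data.frame(name = "troch_med", dx = -0.42, dy = 1.00, dz = -0.35, A = 10, w = 0.22),
    data.frame(name = "troch_lat", dx = 0.42, dy = 1.00, dz = -0.35, A = 10, w = 0.22),
    data.frame(name = "epi_med", dx = -1.00, dy = 0.05, dz = -0.20, A = 5, w = 0.30),
    data.frame(name = "epi_lat", dx = 1.00, dy = 0.05, dz = -0.20, A = 5, w = 0.30),
    data.frame(name = "notch", dx = 0.00, dy = -0.75, dz = -0.66, A = -9, w = 0.25)
  )
}

tibia_lobes <- function() {
  rbind(
    data.frame(name = "emin_med", dx = -0.30, dy = 0.02, dz = 1.00, A = 5, w = 0.17),
    data.frame(name = "emin_lat", dx = 0.30, dy = 0.02, dz = 1.00, A = 5, w = 0.17),
    data.frame(name = "post_med", dx = -0.50, dy = -1.00, dz = 0.28, A = 10, w = 0.22),
    data.frame(name = "post_lat", dx = 0.50, dy = -1.00, dz = 0.28, A = 10, w = 0.22),
    data.frame(name = "side_med", dx = -1.00, dy = -0.05, dz = 0.25, A = 7, w = 0.30),
    data.frame(name = "side_lat", dx = 1.00, dy = -0.05, dz = 0.25, A = 7, w = 0.30)
  )
}

# landmark -> (lobe providing the optimization start, axis, sense) or a
# fixed nominal direction for construction landmarks
femur_landmark_map <- function() {
  list(
    FMCP = list(lobe = "post_med", axis = "y", sense = "min"),
    FLCP = list(lobe = "post_lat", axis = "y", sense = "min"),
    FMCD = list(lobe = "dist_med", axis = "z", sense = "min"),
    FLCD = list(lobe = "dist_lat", axis = "z", sense = "min"),
    FMTA = list(lobe = "troch_med", axis = "y", sense = "max"),
    FLTA = list(lobe = "troch_lat", axis = "y", sense = "max"),
    FME = list(lobe = "epi_med", axis = "x", sense = "min"),
    FLE = list(lobe = "epi_lat", axis = "x", sense = "max"),
    FMCPP = list(dir = c(-0.42, -0.85, 0.10)),
    FLCPP = list(dir = c(0.42, -0.85, 0.10)),
    Notch = list(dir = c(0.00, -0.72, -0.62)),
    FMCIP = list(dir = c(-0.20, -0.73, -0.64)),
    FMCEP = list(dir = c(-0.88, -0.38, -0.45)),
    FLCIP = list(dir = c(0.20, -0.73, -0.64)),
    FLCEP = list(dir = c(0.88, -0.38, -0.45))
  )
}

tibia_landmark_map <- function() {
  list(
    TMIE = list(lobe = "emin_med", axis = "z", sense = "max"),
    TLIE = list(lobe = "emin_lat", axis = "z", sense = "max"),
    TMCP = list(lobe = "post_med", axis = "y", sense = "min"),
    TLCP = list(lobe = "post_lat", axis = "y", sense = "min"),
    TMCM = list(lobe = "side_med", axis = "x", sense = "min"),
    TLCL = list(lobe = "side_lat", axis = "x", sense = "max"),
    TMCA = list(dir = c(-0.45, 0.95, 0.30)),
    TLCA = list(dir = c(0.45, 0.95, 0.30))
  )
}

phantom_geometry <- function(spec) {
  if (spec$bone == "femur_like") {
    lobes <- femur_lobes()
    lmap <- femur_landmark_map()
    semi <- c(36, 28, 28)
    center <- c(0, 0, 0)
    crop <- list(axis = 3, sense = "le", value = 18)
  } else {
    lobes <- tibia_lobes()
    lmap <- tibia_landmark_map()
    semi <- c(37, 26, 30)
    center <- c(0, 0, -75)
    crop <- list(axis = 3, sense = "ge", value = -95)
  }
  # condyle offsets displace the posterior lobes (converted to direction
  # units by the mean semi-axis)
  r0 <- mean(semi)
  po <- function(nm, off) {
    i <- which(lobes$name == nm)
    lobes[i, c("dx", "dy", "dz")] <<- lobes[i, c("dx", "dy", "dz")] + off / r0
  }
  po(if (spec$bone == "femur_like") "post_med" else "post_med",
     spec$condyle_offsets$medial)
  po(if (spec$bone == "femur_like") "post_lat" else "post_lat",
     spec$condyle_offsets$lateral)
  lobes$A <- lobes$A * spec$bump_scale
  dirs <- as.matrix(lobes[, c("dx", "dy", "dz")])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(lobes = lobes, dirs = dirs, lmap = lmap, semi = semi * spec$scale,
       center = center * spec$scale, crop = crop,
       A = lobes$A * spec$scale, w = lobes$w)
}

# radius of the phantom surface along unit directions U (rows)
phantom_radius <- function(U, geom) {
  base <- 1 / sqrt((U[, 1] / geom$semi[1])^2 + (U[, 2] / geom$semi[2])^2 +
                     (U[, 3] / geom$semi[3])^2)
  r <- base
  for (k in seq_len(nrow(geom$lobes))) {
    ct <- pmin(pmax(U %*% geom$dirs[k, ], -1), 1)
    theta <- acos(ct)
    r <- r + geom$A[k] * exp(-theta^2 / (2 * geom$w[k]^2))
  }
  as.vector(r)
}

phantom_point <- function(U, geom) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 3)
  U * phantom_radius(U, geom) +
    matrix(geom$center, nrow(U), 3, byrow = TRUE)
}

# local extremum of the continuous surface coordinate, seeded at a lobe
# center; parameterized in the tangent plane of the start direction
phantom_extremum <- function(geom, start_dir, axis, sense, cap = 0.5) {
  u0 <- start_dir / sqrt(sum(start_dir^2))
  e1 <- cross3(u0, if (abs(u0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u0, e1)
  acol <- match(axis, c("x", "y", "z"))
  sgn <- if (sense == "max") -1 else 1
  obj <- function(t) {
    u <- u0 + t[1] * e1 + t[2] * e2
    u <- u / sqrt(sum(u^2))
    ang <- acos(min(max(sum(u * u0), -1), 1))
    pen <- if (ang > cap) 1e4 * (ang - cap)^2 else 0
    sgn * phantom_point(u, geom)[1, acol] + pen
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  u <- u0 + fit$par[1] * e1 + fit$par[2] * e2
  u <- u / sqrt(sum(u^2))
  ang <- acos(min(max(sum(u * u0), -1), 1))
  # verify a genuine interior local extremum: better than a ring of nearby
  # directions, and not pressed against the search cap
  if (ang > 0.9 * cap) stop("phantom lobe extremum escaped its cap; adjust geometry")
  ring <- sapply(seq(0, 2 * pi, length.out = 17)[-17], function(a) {
    du <- 0.02 * (cos(a) * e1 + sin(a) * e2)
    uu <- u + du
    uu <- uu / sqrt(sum(uu^2))
    sgn * phantom_point(uu, geom)[1, acol]
  })
  if (any(ring < sgn * phantom_point(u, geom)[1, acol] - 1e-9)) {
    stop("phantom lobe extremum is not a local extremum; adjust geometry")
  }
  phantom_point(u, geom)[1, ]
}

phantom_truth_landmarks <- function(geom) {
  out <- matrix(NA_real_, length(geom$lmap), 3,
                dimnames = list(names(geom$lmap), NULL))
  for (nm in names(geom$lmap)) {
    entry <- geom$lmap[[nm]]
    if (!is.null(entry$lobe)) {
      start <- geom$dirs[which(geom$lobes$name == entry$lobe), ]
      out[nm, ] <- phantom_extremum(geom, start, entry$axis, entry$sense)
    } else {
      d <- entry$dir / sqrt(sum(entry$dir^2))
      out[nm, ] <- phantom_point(d, geom)[1, ]
    }
  }
  out
}

# measurements computable from the landmarks present in `coords`
truth_measurements <- function(coords, frame, catalog = measurement_catalog()) {
  have <- rownames(coords)
  need <- lapply(seq_len(nrow(catalog)), function(i) {
    alt <- catalog$alt_pair[[i]]
    c(catalog$landmark_a[i], catalog$landmark_b[i],
      if (!is.null(alt) && !all(is.na(alt))) alt)
  })
  ok <- vapply(need, function(n) all(n %in% have), logical(1))
  if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
  ls <- landmark_set(coords, subject = "truth", observer = "TRUTH")
  df <- measure_all(ls, catalog[ok, , drop = FALSE], frame)
  stats::setNames(df$value_mm, df$abbreviation)
}

make_truth <- function(landmarks, anchors, catalog = measurement_catalog()) {
  frame <- build_reference_frame(anchors["FMCP", ], anchors["FLCP", ])
  structure(list(landmarks = landmarks, frame_anchors = anchors,
                 frame = frame,
                 measurements = truth_measurements(landmarks, frame, catalog)),
            class = "phantom_truth")
}

#' Generate a condyle-like phantom mesh with analytic ground truth
#'
#' The surface is a base ellipsoid with superposed smooth radial Gaussian
#' lobes (two posterior condyles, distal condyles, trochlear lobes,
#' epicondylar prominences and an intercondylar carve for the femur-like
#' phantom; plateau eminences, posterior rims and side prominences for the
#' tibia-like one), cropped by a shaft plane to emulate a limited scan field
#' of view. Every extremum-type landmark is realized as a verified local
#' extremum of the continuous surface near its lobe; construction landmarks
#' sit at fixed surface directions. Ground-truth measurements are evaluated
#' from the analytic landmarks in the frame spanned by the posterior
#' condylar anchors (for the tibia-like phantom the anchors are the
#' corresponding femoral condyle points, which ride along with any later
#' deformation).
#'
#' @param spec a [phantom_spec()].
#' @return list with `mesh` (a [triangle_mesh()]) and `truth`
#'   (class `phantom_truth`: `landmarks` matrix, `frame_anchors`, `frame`,
#'   `measurements`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  geom <- phantom_geometry(spec)
  rmean <- mean(geom$semi)
  nsub <- min(4L, max(2L, ceiling(log2(1.0515 * rmean / spec$mesh_resolution))))
  sph <- icosphere(nsub)
  min_lobe_mm <- min(geom$w) * rmean
  # build surface then check actual resolution against the narrowest lobe
  V <- phantom_point(sph$vertices, geom)
  mesh <- triangle_mesh(V, sph$faces, name = spec$bone, validate = FALSE)
  if (mean_edge_length(mesh) > spec$mesh_resolution * 1.15) {
    # subdivision alone cannot reach the requested resolution: remesh, then
    # re-project every vertex exactly onto the analytic radial surface
    mesh <- isotropic_remesh(mesh, spec$mesh_resolution, iterations = 4)
    U <- sweep(mesh$vertices, 2, geom$center)
    U <- U / sqrt(rowSums(U^2))
    mesh <- triangle_mesh(phantom_point(U, geom), mesh$faces,
                          name = spec$bone, validate = FALSE)
  }
  if (mean_edge_length(mesh) > min_lobe_mm / 2) {
    stop("mesh_resolution too coarse to resolve the narrowest lobe (",
         round(min_lobe_mm, 1), " mm)")
  }
  cr <- geom$crop
  V <- mesh$vertices
  vz <- V[, cr$axis]
  keep_v <- if (cr$sense == "le") vz <= cr$value * spec$scale else
    vz >= cr$value * spec$scale
  keep_f <- keep_v[mesh$faces[, 1]] & keep_v[mesh$faces[, 2]] &
    keep_v[mesh$faces[, 3]]
  used <- sort(unique(as.vector(mesh$faces[keep_f, ])))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  mesh <- clean_mesh(triangle_mesh(V[used, , drop = FALSE],
                                   matrix(remap[mesh$faces[keep_f, ]], ncol = 3),
                                   name = spec$bone, validate = FALSE))
  landmarks <- phantom_truth_landmarks(geom)
  anchors <- if (spec$bone == "femur_like") {
    landmarks[c("FMCP", "FLCP"), , drop = FALSE]
  } else {
    fg <- phantom_geometry(phantom_spec("femur_like", scale = spec$scale,
                                        mesh_resolution = spec$mesh_resolution))
    fl <- fg$lmap
    rbind(
      FMCP = phantom_extremum(fg, fg$dirs[fg$lobes$name == "post_med", ], "y", "min"),
      FLCP = phantom_extremum(fg, fg$dirs[fg$lobes$name == "post_lat", ], "y", "min")
    )
  }
  list(mesh = mesh, truth = make_truth(landmarks, anchors))
}

#' Smoothly deform a phantom, carrying its ground truth along
#'
#' Applies a band-limited random displacement field (a superposition of
#' isotropic Gaussian kernels of width `smoothness`, rescaled so the RMS
#' vertex displacement equals `magnitude`) to the mesh, the truth landmarks
#' and the frame anchors, then recomputes the truth measurements in the
#' deformed anchor frame. `mode = "rigid"` applies a random small axial
#' rotation plus translation instead (an isometry compatible with the
#' table-anchored frame: truth measurements are unchanged).
#' Deformations that flip any triangle (local self-intersection) are
#' rejected with an error.
#'
#' @param mesh phantom [triangle_mesh()].
#' @param truth its `phantom_truth`.
#' @param magnitude RMS displacement in mm (0 = identity).
#' @param smoothness kernel width in mm; must be at least 3 mean edge
#'   lengths so the field is smooth at the mesh scale.
#' @param seed RNG seed.
#' @param mode "elastic" (random smooth field) or "rigid".
#' @param n_kernels number of Gaussian kernels for the elastic field.
#' @return list with deformed `mesh` and updated `truth`.
#' @export
deform_phantom <- function(mesh, truth, magnitude = 2, smoothness = 20,
                           seed = 1L, mode = c("elastic", "rigid"),
                           n_kernels = 12L) {
  mode <- match.arg(mode)
  if (magnitude == 0) return(list(mesh = mesh, truth = truth))
  if (mode == "elastic" && smoothness < 3 * mean_edge_length(mesh)) {
    stop("smoothness must be >= 3 mean edge lengths")
  }
  pts <- rbind(mesh$vertices, truth$landmarks, truth$frame_anchors)
  nv <- nrow(mesh$vertices)
  if (mode == "rigid") {
    # axial rotation + translation: the one rigid freedom a correctly
    # positioned knee has on the scanner table, so the table-anchored
    # reference frame re-derives exactly and measurements are unchanged
    newpts <- with_seed(seed, {
      ang <- stats::runif(1, -0.3, 0.3)
      R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                  3, 3)
      tr <- stats::rnorm(3, sd = magnitude)
      ctr <- colMeans(mesh$vertices)
      sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + tr, `+`)
    })
  } else {
    newpts <- with_seed(seed, {
      lo <- apply(mesh$vertices, 2, min) - smoothness / 2
      hi <- apply(mesh$vertices, 2, max) + smoothness / 2
      centers <- cbind(stats::runif(n_kernels, lo[1], hi[1]),
                       stats::runif(n_kernels, lo[2], hi[2]),
                       stats::runif(n_kernels, lo[3], hi[3]))
      coef <- matrix(stats::rnorm(3 * n_kernels), n_kernels, 3)
      field <- function(p) {
        d2 <- outer(rowSums(p^2), rowSums(centers^2), `+`) -
          2 * p %*% t(centers)
        exp(-d2 / (2 * smoothness^2)) %*% coef
      }
      disp <- field(pts)
      rms <- sqrt(mean(rowSums(disp[seq_len(nv), , drop = FALSE]^2)))
      if (rms < 1e-12) stop("degenerate displacement field")
      pts + disp * (magnitude / rms)
    })
  }
  newmesh <- triangle_mesh(newpts[seq_len(nv), , drop = FALSE], mesh$faces,
                           name = mesh$name, validate = FALSE)
  flip <- rowSums(face_normals(newmesh)$normals * face_normals(mesh)$normals)
  if (any(flip < 0)) {
    stop("deformation flips ", sum(flip < 0), " triangle(s); reduce magnitude")
  }
  nl <- nrow(truth$landmarks)
  newlm <- newpts[nv + seq_len(nl), , drop = FALSE]
  rownames(newlm) <- rownames(truth$landmarks)
  newanch <- newpts[nv + nl + seq_len(nrow(truth$frame_anchors)), , drop = FALSE]
  rownames(newanch) <- rownames(truth$frame_anchors)
  list(mesh = newmesh, truth = make_truth(newlm, newanch))
}

#' Generate a full knee phantom (femur + tibia) and deformed subjects
#'
#' Convenience wrapper producing one template knee and `n_subjects` subject
#' knees, each obtained by applying a single smooth random displacement
#' field jointly to both bones (so the femur-derived reference frame remains
#' consistent for the tibia truth).
#'
#' @param n_subjects number of deformed subject knees.
#' @param magnitude,smoothness deformation parameters (mm), see
#'   [deform_phantom()].
#' @param seed base RNG seed; subject s uses seed + s.
#' @param mesh_resolution target edge length (mm).
#' @param scale global size factor.
#' @return list with `template` and `subjects`; each knee is a list with
#'   `femur` (mesh), `tibia` (mesh), and `truth` (combined landmarks of both
#'   bones, anchors, frame, all 15 measurements).
#' @export
generate_knee_cohort <- function(n_subjects = 6, magnitude = 2,
                                 smoothness = 20, seed = 42L,
                                 mesh_resolution = 2.5, scale = 1) {
  fem <- generate_phantom(phantom_spec("femur_like", scale = scale,
                                       mesh_resolution = mesh_resolution))
  tib <- generate_phantom(phantom_spec("tibia_like", scale = scale,
                                       mesh_resolution = mesh_resolution))
  combine_truth <- function(ft, tt) {
    make_truth(rbind(ft$landmarks, tt$landmarks), ft$frame_anchors)
  }
  template <- list(femur = fem$mesh, tibia = tib$mesh,
                   truth = combine_truth(fem$truth, tib$truth))
  subjects <- lapply(seq_len(n_subjects), function(s) {
    df <- deform_phantom(fem$mesh, fem$truth, magnitude, smoothness,
                         seed = seed + s)
    dt <- deform_phantom(tib$mesh, tib$truth, magnitude, smoothness,
                         seed = seed + s)
    df$mesh$name <- sprintf("subject%02d_femur", s)
    dt$mesh$name <- sprintf("subject%02d_tibia", s)
    list(femur = df$mesh, tibia = dt$mesh,
         truth = combine_truth(df$truth, dt$truth))
  })
  names(subjects) <- sprintf("subject%02d", seq_len(n_subjects))
  list(template = template, subjects = subjects)
}

#' Simulate expert observers annotating a phantom
#'
#' Each observer receives a persistent bias per landmark, drawn in the
#' surface tangent plane with per-component SD `sigma_inter`; each repeat
#' adds tangent-plane jitter with per-component SD `sigma_intra`. All
#' simulated annotations are projected back onto the mesh surface, as real
#' annotations are surface points. Defaults emulate a three-observer panel
#' in which the first observer annotates three times.
#'
#' @param truth a `phantom_truth` (landmarks in the mesh's coordinates).
#' @param mesh the phantom [triangle_mesh()] the annotations live on.
#' @param n_observers number of observers.
#' @param n_repeats integer vector of repeats per observer (recycled).
#' @param sigma_intra,sigma_inter tangent-plane noise SDs (mm/component).
#' @param seed RNG seed.
#' @param subject subject id stamped on the output sets.
#' @return list of [landmark_set()] objects (observers `obs1..obsN`).
#' @export
simulate_observers <- function(truth, mesh, n_observers = 3,
                               n_repeats = c(3, 1, 1), sigma_intra = 1.0,
                               sigma_inter = 1.5, seed = 1L,
                               subject = mesh$name) {
  if (sigma_intra < 0 || sigma_inter < 0) stop("sigmas must be >= 0")
  lm <- truth$landmarks[rownames(truth$landmarks) %in%
                          landmark_bones(mesh, truth), , drop = FALSE]
  hit <- closest_on_surface(mesh, lm)
  fn <- face_normals(mesh)$normals[hit$face, , drop = FALSE]
  tang <- lapply(seq_len(nrow(lm)), function(i) {
    n <- fn[i, ]
    e1 <- cross3(n, if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    e1 <- e1 / sqrt(sum(e1^2))
    list(e1 = e1, e2 = cross3(n, e1))
  })
  reps <- rep_len(n_repeats, n_observers)
  with_seed(seed, {
    out <- list()
    for (o in seq_len(n_observers)) {
      bias <- matrix(stats::rnorm(2 * nrow(lm), sd = sigma_inter), ncol = 2)
      for (r in seq_len(reps[o])) {
        jit <- matrix(stats::rnorm(2 * nrow(lm), sd = sigma_intra), ncol = 2)
        pts <- lm
        for (i in seq_len(nrow(lm))) {
          d <- (bias[i, 1] + jit[i, 1]) * tang[[i]]$e1 +
            (bias[i, 2] + jit[i, 2]) * tang[[i]]$e2
          pts[i, ] <- hit$points[i, ] + d
        }
        proj <- closest_on_surface(mesh, pts)
        coords <- proj$points
        rownames(coords) <- rownames(lm)
        out[[length(out) + 1L]] <- landmark_set(
          coords, subject = subject, observer = paste0("obs", o),
          frame = "RAW", repeat_id = r)
      }
    }
    out
  })
}

# which truth landmarks live on this mesh (femur vs tibia acronyms)
landmark_bones <- function(mesh, truth) {
  cat <- landmark_catalog()
  bone <- if (grepl("tibia", mesh$name)) "tibia" else "femur"
  cat$acronym[cat$bone == bone]
}
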