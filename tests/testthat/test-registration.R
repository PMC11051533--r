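test_that("registration config validates the stiffness schedule", {
  expect_error(registration_config(elastic_steps = 3,
                                   stiffness_schedule = c(1, 2, 3)),
               "decreasing")
  expect_error(registration_config(elastic_steps = 2,
                                   stiffness_schedule = c(1, -1)),
               "decreasing|positive")
  cfg <- registration_config()
  expect_s3_class(cfg, "registration_config")
  expect_true(all(diff(cfg$stiffness_schedule) < 0))
})

test_that("rigid transforms validate, apply and compose correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  set.seed(5)
  R1 <- random_rotation(); R2 <- random_rotation()
  a <- rigid_transform(R1, c(1, 2, 3))
  b <- rigid_transform(R2, c(-1, 0, 4))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(compose_transform(b, a), p),
               apply_transform(b, apply_transform(a, p)), tolerance = 1e-12)
})

test_that("rigid alignment is identity-stable and noise-robust", {
  ph <- generate_phantom(phantom_spec("tibia_like"))$mesh
  tf <- rigid_align(ph, ph)
  expect_lt(max(abs(tf$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf$translation)), 1e-6)
  expect_lt(attr(tf, "rms"), 1e-8)
  set.seed(8)
  noisy <- map_vertices(ph, function(v) v + matrix(rnorm(length(v), sd = 0.1),
                                                   ncol = 3))
  tf2 <- rigid_align(ph, noisy)
  expect_lt(mean(closest_on_surface(noisy,
                                    apply_transform(tf2, ph)$vertices)$dist),
            0.2)
})

test_that("elastic registration tracks a smooth radial inflation", {
  s <- icosphere(3, 10)
  target <- map_vertices(s, function(v) v * 1.05)
  cm <- elastic_register(s, target, rigid = FALSE)
  expect_lt(mean(cm$residual), 0.1 * mean_edge_length(s))
  # deformed radius should be close to 10.5 everywhere
  r <- sqrt(rowSums(cm$vertices^2))
  expect_lt(max(abs(r - 10.5)), 0.3)
})

test_that("elastic objective is non-increasing within each stiffness level", {
  # closed surfaces with fully valid correspondences: the alternating
  # match/solve scheme is monotone when no matches are gated in or out
  s1 <- icosphere(3, 10)
  target <- map_vertices(s1, function(v) v * (1 + 0.08 * sin(v[, 3] / 4)))
  cm <- elastic_register(s1, target, rigid = FALSE)
  tr <- attr(cm, "objective_trace")
  for (a in unique(tr[, "alpha"])) {
    obj <- tr[tr[, "alpha"] == a, "objective"]
    if (length(obj) > 1) {
      expect_true(all(diff(obj) <= 1e-6 * (1 + abs(obj[-length(obj)]))))
    }
  }
})

test_that("corresponded output rotates with the target", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  d <- deform_phantom(ph$mesh, ph$truth, magnitude = 1.5, smoothness = 25,
                      seed = 9)
  cm <- elastic_register(ph$mesh, d$mesh)
  set.seed(10)
  R <- random_rotation()
  tf <- rigid_transform(R, c(4, -2, 7))
  cm_rot <- elastic_register(ph$mesh, apply_transform(tf, d$mesh))
  expect_lt(mean(sqrt(rowSums((cm_rot$vertices -
                                 apply_transform(tf, cm$vertices))^2))),
            0.05)
})

test_that("mean shape averages corresponded vertices", {
  s <- icosphere(2, 10)
  one <- as_corresponded(s)
  expect_equal(mean_shape(list(one))$vertices, s$vertices)
  # mirrored pair averages onto the mirror plane
  mirrored <- s
  mirrored$vertices[, 1] <- -mirrored$vertices[, 1] + 4
  pair <- mean_shape(list(as_corresponded(s), as_corresponded(mirrored)))
  expect_equal(unique(round(pair$vertices[, 1], 9)), 2)
  # analytic mean radius of three inflated spheres
  radii <- c(9, 10, 11)
  spheres <- lapply(radii, function(r) as_corresponded(
    map_vertices(s, function(v) v * r / 10)))
  ms <- mean_shape(spheres)
  expect_equal(mean(sqrt(rowSums(ms$vertices^2))), 10, tolerance = 1e-6)
  bad <- as_corresponded(icosphere(1, 10))
  expect_error(mean_shape(list(one, bad)), "topology")
})

test_that("triangle distortion is similarity-invariant and flags shear", {
  m <- tetra_mesh()
  rep0 <- triangle_distortion(as_corresponded(m), m)
  expect_equal(rep0$metric, rep(1, 4), tolerance = 1e-9)
  expect_length(rep0$flagged_triangles, 0)
  scaled <- as_corresponded(map_vertices(m, function(v) 2 * v))
  expect_equal(triangle_distortion(scaled, m)$metric, rep(1, 4),
               tolerance = 1e-9)
  # shear one triangle 10:1 along x: closed-form singular values of
  # diag(10, 1) give condition number 10
  sheared <- m
  sheared$vertices <- m$vertices
  sheared$vertices[2, ] <- c(10, 0, 0)   # stretches faces touching vertex 2
  repS <- triangle_distortion(as_corresponded(sheared), m)
  f1 <- which(apply(m$faces == 2, 1, any))
  expect_true(all(repS$metric[f1] > 5))
  expect_setequal(repS$flagged_triangles, f1)
  # the untouched face keeps metric 1
  expect_equal(repS$metric[-f1], rep(1, 4 - length(f1)), tolerance = 1e-9)
})
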