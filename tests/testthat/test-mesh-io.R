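test_that("mesh constructor enforces invariants", {
  expect_error(triangle_mesh(matrix(0, 0, 3), matrix(1L, 1, 3)), "no vertices")
  v <- diag(3)
  expect_error(triangle_mesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  m <- tetra_mesh()
  expect_s3_class(validate_mesh(m), "triangle_mesh")
})

test_that("PLY round-trips preserve topology and coordinates", {
  m <- tetra_mesh()
  for (binary in c(FALSE, TRUE)) {
    p <- tempfile(fileext = ".ply")
    write_mesh(m, p, binary = binary)
    m2 <- read_mesh(p)
    expect_equal(nrow(m2$vertices), 4)
    expect_equal(nrow(m2$faces), 4)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-5)
    unlink(p)
  }
})

test_that("STL cube welds to 8 unique vertices", {
  cube <- unit_cube_mesh()
  for (binary in c(FALSE, TRUE)) {
    p <- tempfile(fileext = ".stl")
    write_mesh(cube, p, binary = binary)   # STL stores a triangle soup
    m <- read_mesh(p)
    expect_equal(nrow(m$vertices), 8)
    expect_equal(nrow(m$faces), 12)
    expect_equal(abs(mesh_volume(m)), 1, tolerance = 1e-9)
    unlink(p)
  }
})

test_that("PLY -> OBJ -> PLY chain preserves vertex count and coordinates", {
  m <- icosphere(2, 5)
  p1 <- tempfile(fileext = ".ply")
  p2 <- tempfile(fileext = ".obj")
  p3 <- tempfile(fileext = ".ply")
  write_mesh(m, p1)
  write_mesh(read_mesh(p1), p2)
  write_mesh(read_mesh(p2), p3)
  m3 <- read_mesh(p3)
  expect_equal(nrow(m3$vertices), nrow(m$vertices))
  expect_lt(max(abs(m3$vertices - m$vertices)), 1e-5)
  unlink(c(p1, p2, p3))
})

test_that("writing an invalid mesh errors", {
  m <- tetra_mesh()
  m$faces <- matrix(integer(0), 0, 3)
  expect_error(write_mesh(m, tempfile(fileext = ".ply")), "no faces")
})

test_that("vertex normals point outward on a sphere and follow the winding", {
  s <- icosphere(3, 1)
  n <- vertex_normals(s)
  expect_gt(min(rowSums(n * s$vertices)), 0.99)
  flipped <- triangle_mesh(s$vertices, s$faces[, c(1, 3, 2)])
  expect_equal(vertex_normals(flipped), -n, tolerance = 1e-12)
})

test_that("normals of a planar patch equal the plane normal", {
  v <- as.matrix(expand.grid(x = 0:3, y = 0:3))
  v <- cbind(v, 0)
  idx <- function(i, j) i + 1 + 4 * j
  f <- do.call(rbind, lapply(0:2, function(j) do.call(rbind, lapply(0:2,
    function(i) rbind(c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                      c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))))))
  m <- triangle_mesh(v, f)
  n <- vertex_normals(m)
  expect_equal(n, matrix(rep(c(0, 0, 1), each = 16), ncol = 3),
               tolerance = 1e-12)
})

test_that("vertex normals rotate with the mesh", {
  set.seed(11)
  m <- generate_phantom(phantom_spec("femur_like"))$mesh
  R <- random_rotation()
  n1 <- vertex_normals(m) %*% t(R)
  n2 <- vertex_normals(apply_transform(rigid_transform(R), m))
  expect_lt(max(abs(n1 - n2)), 1e-6)
})

test_that("geodesic neighborhoods match Dijkstra and are monotone in radius", {
  set.seed(3)
  m <- icosphere(2, 10)
  g <- mesh_graph(m)
  for (center in sample(nrow(m$vertices), 5)) {
    d_oracle <- oracle_geodesic(m, center, 12)
    prev <- integer(0)
    for (r in c(3, 6, 12)) {
      nb <- geodesic_neighborhood(m, center, r, graph = g)
      expect_setequal(nb$members, which(d_oracle <= r))
      expect_true(all(prev %in% nb$members))   # monotone in radius
      prev <- nb$members
    }
  }
  tiny <- geodesic_neighborhood(m, 1, 1e-3)
  expect_identical(tiny$members, 1L)
  all_of_it <- geodesic_neighborhood(m, 1, 1e4)
  expect_equal(length(all_of_it$members), nrow(m$vertices))
  expect_error(geodesic_neighborhood(m, 0, 1), "out of range")
})

test_that("isotropic remeshing concentrates edge lengths near the target", {
  s <- icosphere(3, 10)  # mean edge ~1.5
  r <- isotropic_remesh(s, 2.0, iterations = 4)
  expect_lt(abs(mean_edge_length(r) - 2.0) / 2.0, 0.3)
  expect_lt(abs(mesh_volume(r) / mesh_volume(s) - 1), 0.02)
  # near-fixpoint on an already isotropic mesh
  r2 <- isotropic_remesh(r, 2.0, iterations = 2)
  expect_lt(abs(mean_edge_length(r2) - mean_edge_length(r)) /
              mean_edge_length(r), 0.1)
  expect_error(isotropic_remesh(s, 1e4), "degenerate")
})
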