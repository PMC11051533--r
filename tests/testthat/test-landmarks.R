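test_that("the landmark catalog is complete and internally consistent", {
  cat <- landmark_catalog()
  expect_equal(nrow(cat), 23)
  expect_false(anyDuplicated(cat$acronym) > 0)
  expect_setequal(unique(cat$bone), c("femur", "tibia"))
  expect_equal(sum(cat$bone == "femur"), 15)
  expect_equal(sum(cat$bone == "tibia"), 8)
  # construction landmarks are propagate-only; extremum landmarks carry a sense
  refined <- cat$refine_axis != "none"
  expect_true(all(cat$refine_sense[refined] %in% c("min", "max")))
  expect_true(all(cat$refine_sense[!refined] == "none"))
  expect_true(all(c("FMCIP", "FMCEP", "FLCIP", "FLCEP", "FMCPP", "FLCPP",
                    "TMCA", "TLCA") %in% cat$acronym[!refined]))
})

test_that("landmark sets validate and round-trip through JSON and CSV", {
  coords <- rbind(FMCP = c(1, 2, 3), FLCP = c(4, 5, 6))
  ls <- landmark_set(coords, subject = "s1", observer = "obs1")
  expect_error(landmark_set(unname(coords)), "rownames")
  expect_error(landmark_set(rbind(FMCP = c(1, NA, 3))), "finite")
  pj <- tempfile(fileext = ".json")
  write_landmarks(ls, pj)
  ls2 <- read_landmarks(pj)
  expect_equal(ls2$coordinates, ls$coordinates)
  expect_equal(ls2$observer, "obs1")
  pc <- tempfile(fileext = ".csv")
  write_landmarks(list(ls, landmark_set(coords + 1, "s1", "obs2")), pc)
  lst <- read_landmarks(pc)
  expect_length(lst, 2)
  expect_equal(sort(vapply(lst, `[[`, "", "observer")), c("obs1", "obs2"))
  unlink(c(pj, pc))
})

test_that("propagation is exact for identity and vertex-coincident landmarks", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  cm <- as_corresponded(ph$mesh)
  k <- c(10L, 200L, 1500L)
  co <- ph$mesh$vertices[k, ]
  rownames(co) <- c("A", "B", "C")
  ls <- landmark_set(co, subject = "s", observer = "o")
  out <- propagate_landmark(ls, cm, cm)
  expect_equal(out$coordinates, ls$coordinates, tolerance = 1e-9,
               ignore_attr = TRUE)
  # vertex k on the source maps to vertex k on a deformed destination
  d <- deform_phantom(ph$mesh, ph$truth, 1.5, 25, seed = 2)
  dest <- as_corresponded(d$mesh)
  out2 <- propagate_landmark(ls, cm, dest)
  expect_equal(out2$coordinates, d$mesh$vertices[k, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("propagated phantom apex lands near the destination apex", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  d <- deform_phantom(ph$mesh, ph$truth, 2, 20, seed = 4)
  cm_src <- as_corresponded(ph$mesh)
  cm_dst <- as_corresponded(d$mesh)  # same topology: material correspondence
  ls <- landmark_set(rbind(FMCP = ph$truth$landmarks["FMCP", ]), "s", "o")
  out <- propagate_landmark(ls, cm_src, cm_dst)
  expect_lt(sqrt(sum((out$coordinates["FMCP", ] -
                        d$truth$landmarks["FMCP", ])^2)), 2)
})

test_that("expert mean weights observers equally regardless of repeats", {
  mk <- function(x, obs, rep) {
    landmark_set(rbind(P = c(x, 0, 0)), "s", obs, repeat_id = rep)
  }
  obs <- list(mk(0, "a", 1), mk(0, "a", 2), mk(0, "a", 3), mk(3, "b", 1))
  m <- expert_mean_landmarks(obs)
  expect_equal(unname(m$coordinates["P", ]), c(1.5, 0, 0))
  # three observers at the corners of an equilateral triangle -> centroid
  tri <- list(
    landmark_set(rbind(P = c(1, 0, 0)), "s", "a"),
    landmark_set(rbind(P = c(-0.5, sqrt(3) / 2, 0)), "s", "b"),
    landmark_set(rbind(P = c(-0.5, -sqrt(3) / 2, 0)), "s", "c")
  )
  expect_equal(unname(expert_mean_landmarks(tri)$coordinates["P", ]),
               c(0, 0, 0), tolerance = 1e-12)
  # single observation is the identity
  expect_equal(expert_mean_landmarks(obs[4])$coordinates,
               obs[[4]]$coordinates)
  # missing acronym for one observer is an error naming the gap
  bad <- list(obs[[1]], landmark_set(rbind(Q = c(0, 0, 0)), "s", "b"))
  expect_error(expert_mean_landmarks(bad), "missing landmarks")
})

test_that("seed table snapping matches brute-force nearest vertex", {
  set.seed(21)
  ph <- generate_phantom(phantom_spec("tibia_like"))
  mesh <- ph$mesh
  pts <- mesh$vertices[sample(nrow(mesh$vertices), 10), ] +
    matrix(rnorm(30, sd = 0.5), 10, 3)
  rownames(pts) <- paste0("L", 1:10)
  seeds <- build_seed_table(mesh, landmark_set(pts, "s", "o"))
  brute <- apply(pts, 1, function(p) {
    d2 <- rowSums((mesh$vertices - matrix(p, nrow(mesh$vertices), 3,
                                          byrow = TRUE))^2)
    which(d2 == min(d2))[1]   # lowest index on ties
  })
  expect_equal(unname(seeds), unname(brute))
  # a landmark exactly at a vertex snaps to that vertex
  one <- landmark_set(rbind(X = mesh$vertices[77, ]), "s", "o")
  expect_equal(unname(build_seed_table(mesh, one)), 77L)
})

test_that("extremum refinement finds the distal pole of a sphere", {
  s <- icosphere(3, 10)
  frame <- reference_frame()
  cat <- landmark_catalog()
  def <- cat[cat$acronym == "FMCD", ]   # most distal: minimal z
  lower_cap <- which(s$vertices[, 3] < -7)
  set.seed(2)
  for (seed_v in sample(lower_cap, 4)) {
    v <- optimize_extremum(s, seed_v, def, frame, search_radius = pi * 10)
    expect_equal(s$vertices[v, 3], min(s$vertices[, 3]), tolerance = 1e-9)
  }
  # the extreme vertex is a fixpoint
  vstar <- optimize_extremum(s, lower_cap[1], def, frame, pi * 10)
  expect_identical(optimize_extremum(s, vstar, def, frame, pi * 10), vstar)
  expect_error(optimize_extremum(s, 1, cat[cat$acronym == "Notch", ], frame,
                                 10), "not extremum-defined")
  expect_error(optimize_extremum(s, 10 * nrow(s$vertices), def, frame, 10),
               "out of range")
})

test_that("refinement never regresses, is idempotent and monotone in radius", {
  set.seed(31)
  ph <- generate_phantom(phantom_spec("femur_like"))
  mesh <- ph$mesh
  frame <- ph$truth$frame
  g <- mesh_graph(mesh)
  cat <- landmark_catalog()
  refined <- cat[cat$bone == "femur" & cat$refine_axis != "none", ]
  for (i in seq_len(nrow(refined))) {
    def <- refined[i, ]
    seed_v <- nearest_vertex(mesh, ph$truth$landmarks[def$acronym, ] +
                               rnorm(3, sd = 2))
    coords <- to_frame(mesh$vertices, frame)
    ax <- match(def$refine_axis, c("x", "y", "z"))
    sgn <- if (def$refine_sense == "min") -1 else 1
    v5 <- optimize_extremum(mesh, seed_v, def, frame, 5, graph = g)
    v10 <- optimize_extremum(mesh, seed_v, def, frame, 10, graph = g)
    expect_gte(sgn * coords[v5, ax], sgn * coords[seed_v, ax])
    expect_gte(sgn * coords[v10, ax], sgn * coords[v5, ax])  # monotone
    expect_identical(optimize_extremum(mesh, v10, def, frame, 10, graph = g),
                     v10)                                    # idempotent
  }
})

test_that("automated annotation of the template equals its own seeds", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  cat <- landmark_catalog()
  fcat <- cat[cat$bone == "femur", ]
  truth_ls <- landmark_set(ph$truth$landmarks, "tmpl", "TRUTH")
  seeds <- build_seed_table(ph$mesh, truth_ls)
  auto <- annotate_subject(as_corresponded(ph$mesh), seeds, fcat,
                           frame = ph$truth$frame)
  expect_equal(auto$observer, "AUTO")
  # every coordinate is a mesh vertex
  idx <- nearest_vertex(ph$mesh, auto$coordinates)
  expect_equal(auto$coordinates, ph$mesh$vertices[idx, ], ignore_attr = TRUE)
  # construction landmarks stay at their seeds; refined ones stay close
  # (the seed is already near the extremum)
  seed_pos <- ph$mesh$vertices[seeds[fcat$acronym], ]
  d <- sqrt(rowSums((auto$coordinates[fcat$acronym, ] - seed_pos)^2))
  keep <- fcat$refine_axis == "none"
  expect_equal(max(d[keep]), 0)
  expect_lt(max(d), 2 * mean_edge_length(ph$mesh))
})
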