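test_that("phantom generation is deterministic and scales homogeneously", {
  a <- generate_phantom(phantom_spec("femur_like", seed = 5))
  b <- generate_phantom(phantom_spec("femur_like", seed = 5))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$truth$landmarks, b$truth$landmarks)
  big <- generate_phantom(phantom_spec("femur_like", scale = 2))
  expect_equal(big$truth$measurements, 2 * a$truth$measurements,
               tolerance = 1e-6)
  expect_error(generate_phantom(phantom_spec("tibia_like",
                                             mesh_resolution = 8)),
               "too coarse")
})

test_that("extremum landmarks are realized on the mesh near their lobes", {
  for (bone in c("femur_like", "tibia_like")) {
    ph <- generate_phantom(phantom_spec(bone))
    cat <- landmark_catalog()
    bcat <- cat[cat$bone == sub("_like", "", bone) &
                  cat$refine_axis != "none", ]
    el <- mean_edge_length(ph$mesh)
    co <- to_frame(ph$mesh$vertices, ph$truth$frame)
    tco <- to_frame(ph$truth$landmarks, ph$truth$frame)
    for (i in seq_len(nrow(bcat))) {
      acr <- bcat$acronym[i]
      # the mesh vertex that is most extreme within the lobe region lies
      # within about one edge length of the analytic truth
      near <- which(sqrt(rowSums((ph$mesh$vertices -
        matrix(ph$truth$landmarks[acr, ], nrow(ph$mesh$vertices), 3,
               byrow = TRUE))^2)) < 8)
      ax <- match(bcat$refine_axis[i], c("x", "y", "z"))
      val <- co[near, ax]
      if (bcat$refine_sense[i] == "min") val <- -val
      vbest <- near[which.max(val)]
      expect_lt(sqrt(sum((ph$mesh$vertices[vbest, ] -
                            ph$truth$landmarks[acr, ])^2)), 1.5 * el)
      # and the truth itself is at least as extreme as any nearby vertex
      tv <- tco[acr, ax]
      if (bcat$refine_sense[i] == "min") tv <- -tv
      expect_gte(tv, max(val) - 0.05)
    }
  }
})

test_that("deformation carries the truth along and rejects flips", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  id <- deform_phantom(ph$mesh, ph$truth, magnitude = 0)
  expect_identical(id$mesh$vertices, ph$mesh$vertices)
  # rigid mode is an isometry: measurements unchanged
  rg <- deform_phantom(ph$mesh, ph$truth, magnitude = 2, seed = 3,
                       mode = "rigid")
  expect_equal(rg$truth$measurements, ph$truth$measurements,
               tolerance = 1e-9)
  # elastic mode: RMS vertex displacement equals the requested magnitude,
  # and truth landmarks move by a comparable amount
  el <- deform_phantom(ph$mesh, ph$truth, magnitude = 2, smoothness = 20,
                       seed = 3)
  rms <- sqrt(mean(rowSums((el$mesh$vertices - ph$mesh$vertices)^2)))
  expect_equal(rms, 2, tolerance = 1e-9)
  lrms <- sqrt(mean(rowSums((el$truth$landmarks - ph$truth$landmarks)^2)))
  expect_lt(abs(lrms - 2) / 2, 0.3)
  expect_error(deform_phantom(ph$mesh, ph$truth, magnitude = 2,
                              smoothness = 1, seed = 1), "smoothness")
  expect_error(deform_phantom(ph$mesh, ph$truth, magnitude = 60,
                              smoothness = 20, seed = 1), "flips")
})

test_that("simulated observers scatter around the surface-projected truth", {
  ph <- generate_phantom(phantom_spec("tibia_like"))
  # zero noise: observations equal the truth projected onto the mesh
  quiet <- simulate_observers(ph$truth, ph$mesh, sigma_intra = 0,
                              sigma_inter = 0, seed = 1)
  proj <- closest_on_surface(ph$mesh, ph$truth$landmarks[
    rownames(quiet[[1]]$coordinates), ])$points
  expect_lt(max(sqrt(rowSums((quiet[[1]]$coordinates - proj)^2))), 1e-9)
  # same seed reproduces the same panel
  p1 <- simulate_observers(ph$truth, ph$mesh, seed = 9)
  p2 <- simulate_observers(ph$truth, ph$mesh, seed = 9)
  expect_identical(p1[[4]]$coordinates, p2[[4]]$coordinates)
  # the default panel is three observers, the first with three repeats
  expect_length(p1, 5)
  expect_equal(vapply(p1, `[[`, "", "observer"),
               c("obs1", "obs1", "obs1", "obs2", "obs3"))
})

test_that("the expert mean converges to truth as the panel grows", {
  ph <- generate_phantom(phantom_spec("tibia_like"))
  panel <- simulate_observers(ph$truth, ph$mesh, n_observers = 50,
                              n_repeats = 1, sigma_intra = 0.5,
                              sigma_inter = 1.5, seed = 11)
  em <- expert_mean_landmarks(panel)
  proj <- closest_on_surface(ph$mesh, ph$truth$landmarks[
    rownames(em$coordinates), ])$points
  err <- sqrt(rowSums((em$coordinates - proj)^2))
  expect_lt(mean(err), 3 * 1.6 / sqrt(50) + 0.2)
})

test_that("intra-observer scatter is smaller than inter-observer scatter", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  panel <- simulate_observers(ph$truth, ph$mesh, sigma_intra = 1,
                              sigma_inter = 1.5, seed = 13)
  intra <- landmark_errors(panel[1:3], "INTRA")
  inter <- landmark_errors(panel, "INTER")
  expect_lt(mean(intra$error), mean(inter$error))
})
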