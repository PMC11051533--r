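test_that("reference frame construction aligns the condylar line with x", {
  fr <- build_reference_frame(c(1, 1, 0), c(-1, -1, 0))
  expect_equal(abs(fr$x_axis), c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  expect_equal(fr$z_axis, c(0, 0, 1))
  expect_equal(fr$origin, c(0, 0, 0))
  # orthonormal right-handed
  R <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # condylar line already along x: identity rotation
  fr2 <- build_reference_frame(c(-10, 2, 5), c(10, 2, 5))
  expect_equal(fr2$x_axis, c(1, 0, 0))
  expect_equal(fr2$y_axis, c(0, 1, 0))
  # after alignment the two condylar points share y and z
  pts <- to_frame(rbind(c(1, 1, 0), c(-1, -1, 0)), fr)
  expect_equal(pts[1, c("y", "z")], pts[2, c("y", "z")], tolerance = 1e-12)
  expect_error(build_reference_frame(c(0, 0, 0), c(0, 0, 0)), "coincide")
  expect_error(build_reference_frame(c(0, 0, 0), c(0, 0, 5)), "degenerate")
})

test_that("frame alignment is an isometry and refuses double transforms", {
  set.seed(12)
  coords <- matrix(rnorm(23 * 3, sd = 20), 23, 3)
  rownames(coords) <- landmark_catalog()$acronym
  ls <- landmark_set(coords, "s", "o")
  fr <- build_reference_frame(coords["FMCP", ], coords["FLCP", ])
  al <- to_frame(ls, fr)
  expect_equal(al$frame, "ALIGNED")
  expect_equal(as.vector(dist(al$coordinates)), as.vector(dist(coords)),
               tolerance = 1e-9)
  expect_error(to_frame(al, fr), "already ALIGNED")
  # identity frame leaves coordinates unchanged
  expect_equal(to_frame(ls, reference_frame())$coordinates, coords,
               ignore_attr = TRUE)
})

test_that("axis-projection measurements follow their definitions", {
  cat <- measurement_catalog()
  expect_equal(nrow(cat), 15)
  coords <- rbind(A = c(10, 0, 0), B = c(-30, 4, 7))
  def <- data.frame(abbreviation = "T", landmark_a = "A", landmark_b = "B",
                    axis = "x")
  def$alt_pair <- list(NULL)
  ls <- landmark_set(coords, "s", "o")
  ls$frame <- "ALIGNED"
  expect_equal(compute_measurement(def, ls)$value_mm, 40)
  def$landmark_b <- "A"
  expect_equal(compute_measurement(def, ls)$value_mm, 0)
  expect_error(compute_measurement(def, landmark_set(coords, "s", "o")),
               "ALIGNED")
  def$landmark_b <- "C"
  expect_error(compute_measurement(def, ls), "missing landmark")
})

test_that("the notch measurement averages both condylar pairings", {
  cat <- measurement_catalog()
  def <- cat[cat$abbreviation == "AP notch", ]
  coords <- rbind(FMCP = c(0, -10, 0), FLCP = c(5, -14, 0),
                  Notch = c(2, 3, 0))
  ls <- landmark_set(coords, "s", "o")
  ls$frame <- "ALIGNED"
  expect_equal(compute_measurement(def, ls)$value_mm, (13 + 17) / 2)
})

test_that("measure_all yields 15 homogeneous, contractive measurements", {
  set.seed(4)
  cat <- measurement_catalog()
  coords <- matrix(rnorm(23 * 3, sd = 25), 23, 3)
  rownames(coords) <- landmark_catalog()$acronym
  fr <- build_reference_frame(coords["FMCP", ], coords["FLCP", ])
  ls <- landmark_set(coords, "s", "o")
  res <- measure_all(ls, cat, fr)
  expect_equal(nrow(res), 15)
  expect_true(all(res$value_mm >= 0))
  # doubling about the origin doubles every value (frame rebuilt)
  ls2 <- landmark_set(2 * coords, "s", "o")
  fr2 <- build_reference_frame(2 * coords["FMCP", ], 2 * coords["FLCP", ])
  expect_equal(measure_all(ls2, cat, fr2)$value_mm, 2 * res$value_mm,
               tolerance = 1e-9)
  # projection contraction: value <= Euclidean landmark distance
  for (i in seq_len(nrow(cat))) {
    d <- sqrt(sum((coords[cat$landmark_a[i], ] - coords[cat$landmark_b[i], ])^2))
    if (is.null(cat$alt_pair[[i]])) {
      expect_lte(res$value_mm[res$abbreviation == cat$abbreviation[i]],
                 d + 1e-12)
    }
  }
})

test_that("phantom truth measurements equal hand-computed projections", {
  ph <- generate_phantom(phantom_spec("femur_like"))
  lm <- ph$truth$landmarks
  fr <- ph$truth$frame
  co <- to_frame(lm, fr)
  expect_equal(unname(ph$truth$measurements["PCL"]),
               abs(co["FMCP", "x"] - co["FLCP", "x"]))
  expect_equal(unname(ph$truth$measurements["AP MFC"]),
               abs(co["FMCP", "y"] - co["FMTA", "y"]))
  expect_equal(unname(ph$truth$measurements["PD LFC"]),
               abs(co["FLCPP", "z"] - co["FLCD", "z"]))
  expect_equal(unname(ph$truth$measurements["AP notch"]),
               (abs(co["FMCP", "y"] - co["Notch", "y"]) +
                  abs(co["FLCP", "y"] - co["Notch", "y"])) / 2)
})
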