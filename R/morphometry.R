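#' Reference coordinate frame
#'
#' Orthonormal, right-handed frame: x mediolateral, y anteroposterior,
#' z proximodistal.
#'
#' @param origin 3-vector (mm).
#' @param x_axis,y_axis,z_axis unit 3-vectors.
#' @return object of class `reference_frame`.
#' @export
reference_frame <- function(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                            y_axis = c(0, 1, 0), z_axis = c(0, 0, 1)) {
  R <- cbind(x_axis, y_axis, z_axis)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) {
    stop("frame axes must be orthonormal")
  }
  if (det(R) < 0) stop("frame must be right-handed")
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "reference_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the reference frame from the posterior condylar line
#'
#' The proximodistal z-axis is the scanner table direction (`table_axis`,
#' default the mesh file's +z; knees are assumed correctly positioned, so
#' only axial rotation remains to be corrected). The mediolateral x-axis is
#' the unit projection of the posterior condylar line FMCP->FLCP onto the
#' axial plane, making the condylar line parallel to x; by default +x points
#' from the medial to the lateral condyle (right-knee convention; set
#' `medial_to_lateral = FALSE` for mirrored data). y = z cross x completes a
#' right-handed system (anteroposterior). The origin is the midpoint of the
#' two condylar landmarks.
#'
#' @param fmcp,flcp 3D positions (mm) of the posterior medial / lateral
#'   femoral condyle landmarks.
#' @param table_axis unit proximodistal direction.
#' @param medial_to_lateral orient +x from fmcp toward flcp.
#' @return a [reference_frame()].
#' @export
build_reference_frame <- function(fmcp, flcp, table_axis = c(0, 0, 1),
                                  medial_to_lateral = TRUE) {
  fmcp <- as.numeric(fmcp)
  flcp <- as.numeric(flcp)
  if (all(fmcp == flcp)) stop("condylar landmarks coincide")
  z <- table_axis / sqrt(sum(table_axis^2))
  cl <- flcp - fmcp
  x <- cl - sum(cl * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("degenerate frame: condylar line parallel to table axis")
  x <- x / nx
  if (!medial_to_lateral) x <- -x
  y <- cross3(z, x)
  reference_frame(origin = (fmcp + flcp) / 2, x_axis = x, y_axis = y, z_axis = z)
}

# change of basis into frame coordinates (pure geometry, no class bookkeeping)
frame_coordinates <- function(points, frame) {
  drop1 <- is.null(dim(points))
  if (drop1) points <- matrix(points, ncol = 3)
  R <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  out <- sweep(points, 2, frame$origin) %*% R
  colnames(out) <- c("x", "y", "z")
  if (drop1) drop(out) else out
}

#' Transform landmarks or a mesh into a reference frame
#'
#' Rigid change of basis (distances preserved). Landmark sets are flagged as
#' `ALIGNED`; aligning an already ALIGNED set is an error, so coordinates
#' are never silently double-transformed.
#'
#' @param x a [landmark_set()], [triangle_mesh()], or n x 3 matrix.
#' @param frame a [reference_frame()].
#' @return the same kind of object in frame coordinates.
#' @export
to_frame <- function(x, frame) {
  if (inherits(x, "landmark_set")) {
    if (x$frame == "ALIGNED") stop("landmark set is already ALIGNED")
    out <- x
    coords <- frame_coordinates(x$coordinates, frame)
    rownames(coords) <- rownames(x$coordinates)
    out$coordinates <- coords
    out$frame <- "ALIGNED"
    out
  } else if (inherits(x, "triangle_mesh")) {
    if (identical(attr(x, "frame"), "ALIGNED")) {
      stop("mesh is already ALIGNED")
    }
    out <- map_vertices(x, function(v) frame_coordinates(v, frame))
    attr(out, "frame") <- "ALIGNED"
    out
  } else {
    frame_coordinates(x, frame)
  }
}

#' The morphometric measurement catalog
#'
#' 15 linear measurements of the tibiofemoral joint, each defined as the
#' absolute difference of two landmark coordinates along one reference-frame
#' axis (x mediolateral, y anteroposterior, z proximodistal). The notch
#' anteroposterior size carries an alternative landmark pair and is reported
#' as the mean of both pairings. All 15 entries are computed; the
#' mediolateral notch size is carried with `validated = FALSE` because the
#' landmark studies this catalog descends from report no reference values
#' for it.
#'
#' @param path optional alternative catalog JSON.
#' @return data.frame with one row per measurement (list column `alt_pair`,
#'   logical column `validated`).
#' @export
measurement_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "measurement_catalog.json",
                        package = "kneemark")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cat <- raw$measurements
  cat$validated <- cat$abbreviation != "ML notch"
  rownames(cat) <- NULL
  cat
}

#' Compute one axis-projection measurement
#'
#' @param definition one-row data.frame from [measurement_catalog()].
#' @param landmarks a [landmark_set()] in ALIGNED frame.
#' @return data.frame row: subject, observer, repeat, abbreviation, value_mm.
#' @export
compute_measurement <- function(definition, landmarks) {
  if (landmarks$frame != "ALIGNED") {
    stop("landmarks must be in the ALIGNED frame (see to_frame)")
  }
  axis_col <- match(definition$axis, c("x", "y", "z"))
  pick <- function(acr) {
    if (!acr %in% rownames(landmarks$coordinates)) {
      stop("measurement ", definition$abbreviation, ": missing landmark ", acr)
    }
    landmarks$coordinates[acr, axis_col]
  }
  val <- abs(pick(definition$landmark_a) - pick(definition$landmark_b))
  alt <- definition$alt_pair
  if (is.list(alt)) alt <- alt[[1]]
  if (!is.null(alt) && length(alt) == 2L && !all(is.na(alt))) {
    val2 <- abs(pick(alt[1]) - pick(alt[2]))
    val <- (val + val2) / 2
  }
  data.frame(subject = landmarks$subject, observer = landmarks$observer,
             "repeat" = landmarks$repeat_id,
             abbreviation = definition$abbreviation,
             value_mm = unname(val), check.names = FALSE)
}

#' Compute all catalog measurements for one landmark set
#'
#' @param landmarks a [landmark_set()]; RAW sets are aligned with `frame`
#'   first, ALIGNED sets are used as-is.
#' @param catalog a [measurement_catalog()].
#' @param frame a [reference_frame()] (required for RAW input).
#' @return data.frame with one row per measurement.
#' @export
measure_all <- function(landmarks, catalog = measurement_catalog(),
                        frame = NULL) {
  if (landmarks$frame == "RAW") {
    if (is.null(frame)) stop("RAW landmarks require a reference frame")
    landmarks <- to_frame(landmarks, frame)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    compute_measurement(catalog[i, ], landmarks)
  }))
  rownames(out) <- NULL
  out
}
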