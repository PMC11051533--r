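#' The anatomical landmark catalog
#'
#' Returns the packaged catalog of 23 named landmarks on the distal femur and
#' proximal tibia. Each entry carries the acronym, bone, a textual
#' definition, and the refinement rule: `refine_axis`/`refine_sense` name the
#' reference-frame coordinate and direction of the local extremum the
#' landmark sits at (e.g. most posterior = minimal anteroposterior
#' coordinate), or `"none"` for landmarks defined by view-dependent
#' constructions, which are propagated through correspondences without
#' refinement. `secondary_axis`/`secondary_sense` break exact primary ties
#' for compound definitions.
#'
#' @param path optional path to an alternative catalog JSON.
#' @return data.frame with one row per landmark, plus attributes `version`
#'   and `frame_convention`.
#' @export
landmark_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "landmark_catalog.json", package = "kneemark")
  }
  raw <- jsonlite::fromJSON(path)
  cat <- raw$landmarks
  if (anyDuplicated(cat$acronym)) stop("duplicate acronyms in landmark catalog")
  bad <- cat$refine_axis == "none" & cat$refine_sense != "none"
  if (any(bad)) stop("catalog inconsistency: sense without axis")
  attr(cat, "version") <- raw$version
  attr(cat, "frame_convention") <- raw$frame_convention
  cat
}

#' Construct a set of named landmark coordinates
#'
#' @param coordinates k x 3 numeric matrix with rownames = landmark acronyms
#'   (mm), or a named list of length-3 vectors.
#' @param subject subject identifier.
#' @param observer observer identifier; `"AUTO"` marks machine annotations.
#' @param frame `"RAW"` (scanner/mesh coordinates) or `"ALIGNED"` (reference
#'   frame coordinates).
#' @param repeat_id repeat number for observers annotating multiple times.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(coordinates, subject = "subject", observer = "obs",
                         frame = c("RAW", "ALIGNED"), repeat_id = 1L) {
  frame <- match.arg(frame)
  if (is.list(coordinates) && !is.matrix(coordinates)) {
    coordinates <- do.call(rbind, coordinates)
  }
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be k x 3")
  if (is.null(rownames(coordinates))) stop("coordinates need acronym rownames")
  if (!all(is.finite(coordinates))) stop("non-finite landmark coordinates")
  structure(
    list(subject = as.character(subject), observer = as.character(observer),
         coordinates = coordinates, frame = frame,
         repeat_id = as.integer(repeat_id)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: subject %s, observer %s (repeat %d), %d landmarks, %s frame\n",
              x$subject, x$observer, x$repeat_id, nrow(x$coordinates), x$frame))
  invisible(x)
}

#' Check a landmark set against a catalog
#' @param landmarks a [landmark_set()].
#' @param catalog a [landmark_catalog()] data.frame.
#' @return the landmark set, invisibly; stops listing missing acronyms.
#' @export
check_landmarks <- function(landmarks, catalog = landmark_catalog()) {
  missing <- setdiff(catalog$acronym, rownames(landmarks$coordinates))
  if (length(missing) > 0) {
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  }
  invisible(landmarks)
}

#' Write / read landmark sets as JSON or flat CSV
#'
#' JSON layout: `{subject, observer, repeat, frame, landmarks: {ACRONYM: [x,y,z]}}`.
#' CSV layout: columns subject, observer, repeat, frame, acronym, x, y, z
#' (several sets may share one CSV).
#'
#' @param landmarks a [landmark_set()] (or list of them, CSV only).
#' @param path output file; extension selects the format (.json or .csv).
#' @return `path` invisibly for the writer; for [read_landmarks()] a
#'   [landmark_set()] (JSON) or list of them (CSV).
#' @export
write_landmarks <- function(landmarks, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    stopifnot(inherits(landmarks, "landmark_set"))
    obj <- list(subject = landmarks$subject, observer = landmarks$observer,
                "repeat" = landmarks$repeat_id, frame = landmarks$frame,
                landmarks = apply(landmarks$coordinates, 1, identity,
                                  simplify = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    sets <- if (inherits(landmarks, "landmark_set")) list(landmarks) else landmarks
    df <- do.call(rbind, lapply(sets, function(ls) {
      data.frame(subject = ls$subject, observer = ls$observer,
                 "repeat" = ls$repeat_id, frame = ls$frame,
                 acronym = rownames(ls$coordinates),
                 x = ls$coordinates[, 1], y = ls$coordinates[, 2],
                 z = ls$coordinates[, 3], check.names = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else stop("unsupported landmark file extension: ", ext)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    coords <- do.call(rbind, obj$landmarks)
    landmark_set(coords, subject = obj$subject, observer = obj$observer,
                 frame = obj$frame, repeat_id = obj[["repeat"]])
  } else if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    groups <- split(df, list(df$subject, df$observer, df$`repeat`), drop = TRUE)
    out <- lapply(groups, function(g) {
      coords <- as.matrix(g[, c("x", "y", "z")])
      rownames(coords) <- g$acronym
      landmark_set(coords, subject = g$subject[1], observer = g$observer[1],
                   frame = g$frame[1], repeat_id = g$`repeat`[1])
    })
    names(out) <- NULL
    out
  } else stop("unsupported landmark file extension: ", ext)
}

#' Propagate landmarks through dense correspondences
#'
#' Each landmark is located on the source surface as barycentric coordinates
#' in its nearest triangle, then evaluated in the same triangle of the
#' destination mesh. Source and destination must share the template
#' topology. Landmarks farther than `warn_distance` from the source surface
#' trigger a warning and are projected onto the surface first (projection is
#' implicit in the barycentric lookup).
#'
#' @param landmarks a [landmark_set()] annotated on (or near) the source
#'   surface, in RAW frame.
#' @param source_corresponded,dest_corresponded `corresponded_mesh` objects
#'   sharing one topology.
#' @param warn_distance distance (mm) beyond which a warning is emitted.
#' @return a [landmark_set()] on the destination surface (same observer and
#'   repeat; subject taken from the destination mesh name).
#' @export
propagate_landmark <- function(landmarks, source_corresponded,
                               dest_corresponded, warn_distance = 5) {
  if (!identical(source_corresponded$faces, dest_corresponded$faces)) {
    stop("source and destination do not share the template topology")
  }
  hit <- closest_on_surface(source_corresponded, landmarks$coordinates)
  far <- hit$dist > warn_distance
  if (any(far)) {
    warning("landmark(s) ", paste(rownames(landmarks$coordinates)[far],
                                  collapse = ", "),
            " farther than ", warn_distance, " mm from the source surface; projected")
  }
  dest <- barycentric_points(dest_corresponded, hit$face, hit$bary)
  rownames(dest) <- rownames(landmarks$coordinates)
  landmark_set(dest, subject = dest_corresponded$name,
               observer = landmarks$observer, frame = "RAW",
               repeat_id = landmarks$repeat_id)
}

#' Observer-weighted expert mean landmarks
#'
#' Repeated annotations of one observer are averaged first; the expert mean
#' is then the unweighted mean across observers, so an observer with three
#' repeats counts exactly as much as an observer with one.
#'
#' @param observations list of [landmark_set()] objects for one subject
#'   (observers identified by their `observer` field).
#' @return a [landmark_set()] with observer `"MEAN"`.
#' @export
expert_mean_landmarks <- function(observations) {
  if (length(observations) == 0L) stop("no observations")
  frames <- unique(vapply(observations, `[[`, "", "frame"))
  if (length(frames) != 1L) stop("observations mix RAW and ALIGNED frames")
  acr <- rownames(observations[[1]]$coordinates)
  for (o in observations) {
    gaps <- setdiff(acr, rownames(o$coordinates))
    extra <- setdiff(rownames(o$coordinates), acr)
    if (length(gaps) || length(extra)) {
      stop("observer ", o$observer, " missing landmarks: ",
           paste(c(gaps, extra), collapse = ", "))
    }
  }
  by_obs <- split(observations,
                  vapply(observations, `[[`, "", "observer"))
  per_obs <- lapply(by_obs, function(sets) {
    Reduce(`+`, lapply(sets, function(s) s$coordinates[acr, , drop = FALSE])) /
      length(sets)
  })
  mean_coords <- Reduce(`+`, per_obs) / length(per_obs)
  landmark_set(mean_coords, subject = observations[[1]]$subject,
               observer = "MEAN", frame = frames)
}

#' Snap mean landmarks to mean-shape vertices (seed table)
#'
#' @param mean_shape the cohort mean [triangle_mesh()].
#' @param mean_landmarks a [landmark_set()] of expert mean positions near the
#'   mean-shape surface.
#' @param warn_distance warn when a landmark is farther than this (mm) from
#'   its nearest vertex.
#' @return named integer vector: acronym -> mean-shape vertex index.
#' @export
build_seed_table <- function(mean_shape, mean_landmarks, warn_distance = 5) {
  idx <- nearest_vertex(mean_shape, mean_landmarks$coordinates)
  d <- sqrt(rowSums((mean_shape$vertices[idx, , drop = FALSE] -
                       mean_landmarks$coordinates)^2))
  far <- d > warn_distance
  if (any(far)) {
    warning("seed(s) ", paste(rownames(mean_landmarks$coordinates)[far],
                              collapse = ", "),
            " farther than ", warn_distance, " mm from the mean shape")
  }
  stats::setNames(idx, rownames(mean_landmarks$coordinates))
}

#' Refine a landmark to the locally most extreme vertex
#'
#' Returns the vertex within the geodesic `search_radius` of `seed_vertex`
#' whose reference-frame coordinate along the landmark's `refine_axis` is
#' maximal (sense `"max"`) or minimal (sense `"min"`). Exact primary ties
#' are broken by the secondary axis/sense if the definition has one, then by
#' the lowest vertex index. The search is bounded: an unbounded extremum
#' search would jump across the bone (e.g. to the other condyle), losing the
#' landmark's anatomical identity.
#'
#' @param mesh subject [triangle_mesh()] in RAW coordinates.
#' @param seed_vertex 1-based vertex index of the propagated seed.
#' @param definition one-row data.frame (a [landmark_catalog()] row) with
#'   `refine_axis` != "none".
#' @param frame a [reference_frame()] giving the axis directions.
#' @param search_radius geodesic radius (mm) around the seed.
#' @param graph optional precomputed [mesh_graph()].
#' @return 1-based vertex index of the refined landmark.
#' @export
optimize_extremum <- function(mesh, seed_vertex, definition, frame,
                              search_radius = 10, graph = NULL) {
  if (definition$refine_axis == "none") {
    stop("landmark ", definition$acronym, " is not extremum-defined")
  }
  nv <- nrow(mesh$vertices)
  seed_vertex <- as.integer(seed_vertex)
  if (is.na(seed_vertex) || seed_vertex < 1L || seed_vertex > nv) {
    stop("seed vertex index out of range")
  }
  if (is.null(graph)) graph <- mesh_graph(mesh)
  coords <- frame_coordinates(mesh$vertices, frame)
  axis_col <- match(definition$refine_axis, c("x", "y", "z"))
  primary <- coords[, axis_col]
  if (definition$refine_sense == "min") primary <- -primary
  secondary <- rep(0, nv)
  if (!is.na(definition$secondary_axis) && definition$secondary_axis != "none") {
    sc <- match(definition$secondary_axis, c("x", "y", "z"))
    secondary <- coords[, sc]
    if (definition$secondary_sense == "min") secondary <- -secondary
  }
  nb <- geodesic_neighborhood(mesh, seed_vertex, search_radius, graph = graph)
  cand <- nb$members
  best <- max(primary[cand])
  top <- cand[primary[cand] == best]
  if (length(top) > 1L) {
    top <- top[secondary[top] == max(secondary[top])]
  }
  min(top)
}

#' Automated annotation of one subject
#'
#' Maps every seed vertex to the subject through the shared topology
#' (seed index = subject vertex index on a corresponded mesh), then refines
#' extremum-defined landmarks with [optimize_extremum()] and keeps
#' construction landmarks at their propagated position. Every output
#' coordinate is a subject mesh vertex.
#'
#' @param subject_corresponded the subject's `corresponded_mesh`.
#' @param seeds seed table from [build_seed_table()].
#' @param catalog a [landmark_catalog()].
#' @param frame a [reference_frame()] in the subject's RAW coordinates; when
#'   `NULL` it is built from the propagated FMCP/FLCP seed positions (fully
#'   automated mode).
#' @param search_radius geodesic refinement radius (mm).
#' @return a [landmark_set()] with observer `"AUTO"`.
#' @export
annotate_subject <- function(subject_corresponded, seeds,
                             catalog = landmark_catalog(), frame = NULL,
                             search_radius = 10) {
  missing <- setdiff(catalog$acronym, names(seeds))
  if (length(missing) > 0) {
    stop("seed table lacks landmarks: ", paste(missing, collapse = ", "))
  }
  V <- subject_corresponded$vertices
  if (is.null(frame)) {
    frame <- build_reference_frame(V[seeds[["FMCP"]], ], V[seeds[["FLCP"]], ])
  }
  mesh <- triangle_mesh(V, subject_corresponded$faces,
                        name = subject_corresponded$name, validate = FALSE)
  graph <- mesh_graph(mesh)
  coords <- matrix(NA_real_, nrow(catalog), 3,
                   dimnames = list(catalog$acronym, NULL))
  for (i in seq_len(nrow(catalog))) {
    def <- catalog[i, ]
    vid <- seeds[[def$acronym]]
    if (def$refine_axis != "none") {
      vid <- optimize_extremum(mesh, vid, def, frame,
                               search_radius = search_radius, graph = graph)
    }
    coords[def$acronym, ] <- V[vid, ]
  }
  landmark_set(coords, subject = subject_corresponded$name,
               observer = "AUTO", frame = "RAW")
}
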