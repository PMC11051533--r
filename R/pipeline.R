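#' Subset a landmark set to selected acronyms
#' @param landmarks a [landmark_set()].
#' @param acronyms character vector of landmark names to keep.
#' @return a [landmark_set()] with the selected rows.
#' @export
subset_landmarks <- function(landmarks, acronyms) {
  keep <- intersect(acronyms, rownames(landmarks$coordinates))
  out <- landmarks
  out$coordinates <- landmarks$coordinates[keep, , drop = FALSE]
  out
}

#' Merge landmark sets of one annotation session (e.g. femur + tibia)
#' @param ... [landmark_set()] objects sharing subject/observer/repeat.
#' @return a combined [landmark_set()].
#' @export
merge_landmarks <- function(...) {
  sets <- list(...)
  coords <- do.call(rbind, lapply(sets, `[[`, "coordinates"))
  landmark_set(coords, subject = sets[[1]]$subject,
               observer = sets[[1]]$observer, frame = sets[[1]]$frame,
               repeat_id = sets[[1]]$repeat_id)
}

#' Two-pass correspondence stage: template -> cohort -> mean -> cohort
#'
#' Pass 1 elastically registers the (optionally remeshed) template to every
#' subject, imposing a common topology; the vertex-wise mean of the
#' deformed meshes gives the cohort mean shape. Pass 2 re-registers the
#' mean shape to every subject; the pass-2 deformed meshes are the working
#' correspondences (the mean template is closer to every cohort member than
#' an arbitrary subject, so pass-2 fits are at least as good on average).
#'
#' @param subject_meshes named list of [triangle_mesh()] objects (>= 2).
#' @param config a [registration_config()].
#' @param template a [triangle_mesh()] or the name of a subject; default the
#'   first subject (an arbitrary choice, by design).
#' @param remesh_template isotropically remesh the template first.
#' @param target_edge_length remeshing target (mm); default the template's
#'   own mean edge length.
#' @param verbose print per-stage residual summaries.
#' @return list with `corresponded` (named list of pass-2
#'   `corresponded_mesh`es), `mean_shape` (vertex-wise mean of pass 2),
#'   `template` (as used), and `residuals` (per pass, mean per subject).
#' @export
run_correspondence_stage <- function(subject_meshes,
                                     config = registration_config(),
                                     template = NULL,
                                     remesh_template = TRUE,
                                     target_edge_length = NULL,
                                     verbose = FALSE) {
  if (length(subject_meshes) < 2L) stop("need at least 2 subjects")
  if (is.null(names(subject_meshes))) {
    names(subject_meshes) <- vapply(subject_meshes, `[[`, "", "name")
  }
  tmpl <- if (is.null(template)) {
    subject_meshes[[1]]
  } else if (is.character(template)) {
    subject_meshes[[template]]
  } else template
  if (remesh_template) {
    if (is.null(target_edge_length)) target_edge_length <- mean_edge_length(tmpl)
    tmpl <- isotropic_remesh(tmpl, target_edge_length, iterations = 3)
  }
  tmpl$name <- "template"
  reg_all <- function(tm, tag) {
    out <- lapply(names(subject_meshes), function(nm) {
      r <- elastic_register(tm, subject_meshes[[nm]], config)
      if (verbose) {
        message(sprintf("[%s] %s: mean residual %.3f mm", tag, nm,
                        mean(r$residual)))
      }
      r
    })
    names(out) <- names(subject_meshes)
    out
  }
  pass1 <- reg_all(tmpl, "pass1")
  mean1 <- mean_shape(pass1, name = "mean_shape")
  pass2 <- reg_all(mean1, "pass2")
  mean2 <- mean_shape(pass2, name = "mean_shape")
  list(
    corresponded = pass2,
    mean_shape = mean2,
    template = tmpl,
    residuals = list(
      pass1 = vapply(pass1, function(m) mean(m$residual), numeric(1)),
      pass2 = vapply(pass2, function(m) mean(m$residual), numeric(1))
    )
  )
}

#' Leave-one-out automated annotation of one subject
#'
#' Builds landmark seeds from all other subjects' manual annotations:
#' each annotation set is propagated through the dense correspondences onto
#' the mean shape; per-observer repeats are averaged first and observers
#' weighted equally; the mean landmark is snapped to its nearest mean-shape
#' vertex. The held-out subject is then annotated from those seeds alone,
#' so its automated landmarks are independent of its own manual
#' annotations.
#'
#' @param annotations named list (by subject) of lists of [landmark_set()]s.
#' @param corresponded named list of `corresponded_mesh`es from
#'   [run_correspondence_stage()].
#' @param mean_shape_mesh the cohort mean [triangle_mesh()].
#' @param held_out subject id to annotate.
#' @param catalog a [landmark_catalog()] (or bone subset thereof).
#' @param frame optional [reference_frame()] for extremum refinement; when
#'   NULL it is derived from the held-out subject's propagated condylar
#'   seeds (fully automated femur mode).
#' @param search_radius geodesic refinement radius (mm).
#' @return the held-out subject's automated [landmark_set()] (observer
#'   `"AUTO"`), with the seed table attached as attribute `"seeds"`.
#' @export
run_leave_one_out <- function(annotations, corresponded, mean_shape_mesh,
                              held_out, catalog = landmark_catalog(),
                              frame = NULL, search_radius = 10) {
  if (!held_out %in% names(corresponded)) {
    stop("held-out subject ", held_out, " has no correspondence")
  }
  donors <- setdiff(names(annotations), held_out)
  if (length(donors) == 0L) stop("no donor subjects for seeding")
  mean_corr <- as_corresponded(mean_shape_mesh)
  propagated <- list()
  for (s in donors) {
    for (ls in annotations[[s]]) {
      sub <- subset_landmarks(ls, catalog$acronym)
      propagated[[length(propagated) + 1L]] <-
        propagate_landmark(sub, corresponded[[s]], mean_corr)
    }
  }
  mean_lms <- expert_mean_landmarks(propagated)
  seeds <- build_seed_table(mean_shape_mesh, mean_lms)
  auto <- annotate_subject(corresponded[[held_out]], seeds, catalog,
                           frame = frame, search_radius = search_radius)
  attr(auto, "seeds") <- seeds
  auto
}

#' Full agreement report: intra-/inter-observer and inter-method statistics
#'
#' Reproduces the complete validation design on a cohort of manually
#' annotated and automatically annotated subjects: Euclidean landmark
#' errors and absolute measurement differences for the INTRA (repeats of
#' observer 1), INTER (between observers) and METHOD (automated vs expert
#' mean) comparisons; per-item quartile summaries with 1.5 IQR outlier
#' flagging; per-measurement ICC tables (two-way mixed for intra, two-way
#' random for inter and method, absolute agreement, single rater);
#' Bland-Altman limits per measurement; success-rate curves; per-subject
#' outlier counts. Measurements are computed after aligning each subject
#' with the reference frame derived from its expert mean condylar landmarks
#' (`frame_mode = "expert"`), or from the automated condylar landmarks for
#' a fully operator-independent run (`frame_mode = "auto"`, manual sets
#' still use the expert frame).
#'
#' If no observer has repeated annotations the INTRA comparison is skipped
#' with a warning.
#'
#' @param annotations named list (by subject) of lists of [landmark_set()]s
#'   (RAW frame, full landmark catalog).
#' @param autos named list (by subject) of automated [landmark_set()]s.
#' @param lm_catalog a [landmark_catalog()].
#' @param ms_catalog a [measurement_catalog()].
#' @param frame_mode "expert" or "auto" (frame for automated measurements).
#' @param tol_landmarks,tol_measurements success-curve tolerance grids (mm).
#' @return list of class `agreement_report`; see Details.
#' @export
run_validation <- function(annotations, autos,
                           lm_catalog = landmark_catalog(),
                           ms_catalog = measurement_catalog(),
                           frame_mode = c("expert", "auto"),
                           tol_landmarks = default_tolerances("landmarks"),
                           tol_measurements = default_tolerances("measurements")) {
  frame_mode <- match.arg(frame_mode)
  subjects <- names(annotations)
  if (!all(subjects %in% names(autos))) {
    stop("missing automated annotations for: ",
         paste(setdiff(subjects, names(autos)), collapse = ", "))
  }
  lm_err <- list()
  ms_err <- list()
  manual_ms <- list()
  auto_ms <- list()
  have_intra <- FALSE
  for (s in subjects) {
    obs_sets <- annotations[[s]]
    auto <- autos[[s]]
    emean <- expert_mean_landmarks(obs_sets)
    frame_s <- build_reference_frame(emean$coordinates["FMCP", ],
                                     emean$coordinates["FLCP", ])
    frame_a <- if (frame_mode == "auto") {
      build_reference_frame(auto$coordinates["FMCP", ],
                            auto$coordinates["FLCP", ])
    } else frame_s
    obs_ids <- vapply(obs_sets, `[[`, "", "observer")
    rep1 <- obs_sets[obs_ids == obs_ids[1]]
    if (length(rep1) >= 2L) {
      have_intra <- TRUE
      lm_err[[length(lm_err) + 1L]] <- landmark_errors(rep1, "INTRA")
    }
    lm_err[[length(lm_err) + 1L]] <- landmark_errors(obs_sets, "INTER")
    lm_err[[length(lm_err) + 1L]] <- landmark_errors(obs_sets, "METHOD",
                                                     auto = auto)
    mm <- do.call(rbind, lapply(obs_sets, measure_all, catalog = ms_catalog,
                                frame = frame_s))
    am <- measure_all(auto, ms_catalog, frame_a)
    manual_ms[[s]] <- mm
    auto_ms[[s]] <- am
    mm1 <- mm[mm$observer == obs_ids[1], ]
    if (length(unique(mm1$`repeat`)) >= 2L) {
      ms_err[[length(ms_err) + 1L]] <- measurement_errors(mm1, "INTRA")
    }
    ms_err[[length(ms_err) + 1L]] <- measurement_errors(mm, "INTER")
    ms_err[[length(ms_err) + 1L]] <- measurement_errors(mm, "METHOD", auto = am)
  }
  if (!have_intra) warning("no repeated annotations: INTRA comparison skipped")
  lm_err <- do.call(rbind, lm_err)
  ms_err <- do.call(rbind, ms_err)

  summarize <- function(err) {
    do.call(rbind, lapply(split(err, list(err$item, err$comparison),
                                drop = TRUE), function(g) {
      qs <- quartile_summary(g$error)
      data.frame(item = g$item[1], comparison = g$comparison[1],
                 q1 = qs$q1, median = qs$median, q3 = qs$q3, iqr = qs$iqr,
                 mean = qs$mean, sd = qs$sd, n = qs$n,
                 n_outliers = length(qs$outlier_ids))
    }))
  }
  lm_summary <- summarize(lm_err)
  ms_summary <- summarize(ms_err)
  rownames(lm_summary) <- rownames(ms_summary) <- NULL

  # per-measurement ICC tables
  icc_rows <- list()
  ba <- list()
  for (ab in ms_catalog$abbreviation) {
    # INTRA: subjects x repeats of observer 1
    tabs <- lapply(subjects, function(s) {
      mm <- manual_ms[[s]]
      obs1 <- vapply(annotations[[s]], `[[`, "", "observer")[1]
      r <- mm[mm$abbreviation == ab & mm$observer == obs1, ]
      r$value_mm[order(r$`repeat`)]
    })
    nrep <- unique(lengths(tabs))
    if (length(nrep) == 1L && nrep >= 2L && length(subjects) >= 2L) {
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        abbreviation = ab, comparison = "INTRA",
        icc = icc(do.call(rbind, tabs), "TWO_WAY_MIXED")$value)
    }
    # INTER: subjects x observers (repeat-averaged)
    tabs <- lapply(subjects, function(s) {
      mm <- manual_ms[[s]]
      r <- mm[mm$abbreviation == ab, ]
      agg <- stats::aggregate(value_mm ~ observer, r, mean)
      stats::setNames(agg$value_mm, agg$observer)
    })
    if (length(subjects) >= 2L) {
      obs_all <- sort(unique(unlist(lapply(tabs, names))))
      tab <- do.call(rbind, lapply(tabs, function(t) t[obs_all]))
      if (ncol(tab) >= 2L && !anyNA(tab)) {
        icc_rows[[length(icc_rows) + 1L]] <- data.frame(
          abbreviation = ab, comparison = "INTER",
          icc = icc(tab, "TWO_WAY_RANDOM")$value)
      }
      # METHOD: subjects x (expert mean, automated)
      man <- vapply(subjects, function(s) {
        mm <- manual_ms[[s]]
        r <- mm[mm$abbreviation == ab, ]
        mean(stats::aggregate(value_mm ~ observer, r, mean)$value_mm)
      }, numeric(1))
      aut <- vapply(subjects, function(s) {
        am <- auto_ms[[s]]
        am$value_mm[am$abbreviation == ab]
      }, numeric(1))
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        abbreviation = ab, comparison = "METHOD",
        icc = icc(cbind(manual = man, auto = aut), "TWO_WAY_RANDOM")$value)
      ba[[ab]] <- bland_altman(man, aut)
    }
  }
  icc_table <- do.call(rbind, icc_rows)
  rownames(icc_table) <- NULL

  curves <- function(err, tol) {
    out <- lapply(split(err, err$comparison), function(g) {
      success_rates(g$error, tol, item = g$comparison[1])
    })
    out
  }
  means <- stats::aggregate(error ~ comparison, lm_err, function(e) {
    c(mean = mean(e), sd = stats::sd(e))
  })
  mmeans <- stats::aggregate(error ~ comparison, ms_err, function(e) {
    c(mean = mean(e), sd = stats::sd(e))
  })

  structure(list(
    landmark_errors = lm_err,
    measurement_errors = ms_err,
    landmark_summary = lm_summary,
    measurement_summary = ms_summary,
    icc_table = icc_table,
    bland_altman = ba,
    success_landmarks = curves(lm_err, tol_landmarks),
    success_measurements = curves(ms_err, tol_measurements),
    outlier_counts = rbind(outliers_per_subject(lm_err),
                           outliers_per_subject(ms_err)),
    landmark_means = means,
    measurement_means = mmeans,
    manual_measurements = manual_ms,
    auto_measurements = auto_ms
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement_report\n")
  cat("  landmark mean error (mm) by comparison:\n")
  for (i in seq_len(nrow(x$landmark_means))) {
    cat(sprintf("    %-7s %.2f (SD %.2f)\n", x$landmark_means$comparison[i],
                x$landmark_means$error[i, "mean"],
                x$landmark_means$error[i, "sd"]))
  }
  cat("  measurement mean |difference| (mm) by comparison:\n")
  for (i in seq_len(nrow(x$measurement_means))) {
    cat(sprintf("    %-7s %.2f (SD %.2f)\n",
                x$measurement_means$comparison[i],
                x$measurement_means$error[i, "mean"],
                x$measurement_means$error[i, "sd"]))
  }
  cat(sprintf("  method ICC range: %.3f - %.3f\n",
              min(x$icc_table$icc[x$icc_table$comparison == "METHOD"]),
              max(x$icc_table$icc[x$icc_table$comparison == "METHOD"])))
  invisible(x)
}

#' End-to-end synthetic rehearsal of the whole pipeline
#'
#' Generates a phantom knee cohort (template + deformed subjects), simulates
#' a three-observer manual annotation panel, runs the two-pass
#' correspondence stage per bone, annotates every subject in leave-one-out
#' fashion (femur frame derived from the automated condylar seeds; the
#' tibia shares the femur-derived frame), computes all measurements, and
#' returns the full agreement report together with errors against the
#' generator's analytic ground truth.
#'
#' @param n_subjects cohort size.
#' @param magnitude,smoothness inter-subject deformation (mm).
#' @param sigma_intra,sigma_inter observer noise (mm/component, tangent).
#' @param seed base RNG seed for generation and observers.
#' @param mesh_resolution phantom target edge length (mm).
#' @param search_radius extremum refinement radius (mm).
#' @param config a [registration_config()].
#' @param verbose print stage progress.
#' @return list of class `phantom_rehearsal`: `report` (the
#'   [run_validation()] output), `truth_landmark_errors` (data.frame:
#'   subject, item, error vs analytic truth), `truth_measurement_errors`,
#'   `autos`, `cohort`, `correspondence` (per bone residual summaries).
#' @export
phantom_rehearsal <- function(n_subjects = 6, magnitude = 2, smoothness = 20,
                              sigma_intra = 1.0, sigma_inter = 1.5,
                              seed = 42L, mesh_resolution = 2.5,
                              search_radius = 10,
                              config = registration_config(),
                              verbose = FALSE) {
  cohort <- generate_knee_cohort(n_subjects, magnitude, smoothness,
                                 seed = seed,
                                 mesh_resolution = mesh_resolution)
  catalog <- landmark_catalog()
  ms_catalog <- measurement_catalog()
  fem_cat <- catalog[catalog$bone == "femur", ]
  tib_cat <- catalog[catalog$bone == "tibia", ]

  corr <- list()
  for (bone in c("femur", "tibia")) {
    meshes <- lapply(cohort$subjects, `[[`, bone)
    names(meshes) <- names(cohort$subjects)
    if (verbose) message("correspondence stage: ", bone)
    corr[[bone]] <- run_correspondence_stage(
      meshes, config, template = cohort$template[[bone]],
      remesh_template = TRUE, verbose = verbose)
  }

  annotations <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- names(cohort$subjects)[i]
    kn <- cohort$subjects[[i]]
    sim_f <- simulate_observers(kn$truth, kn$femur,
                                sigma_intra = sigma_intra,
                                sigma_inter = sigma_inter,
                                seed = seed + 101L * i, subject = s)
    sim_t <- simulate_observers(kn$truth, kn$tibia,
                                sigma_intra = sigma_intra,
                                sigma_inter = sigma_inter,
                                seed = seed + 101L * i + 50L, subject = s)
    annotations[[s]] <- Map(merge_landmarks, sim_f, sim_t)
  }

  autos <- list()
  for (s in names(cohort$subjects)) {
    if (verbose) message("leave-one-out annotation: ", s)
    auto_f <- run_leave_one_out(annotations, corr$femur$corresponded,
                                corr$femur$mean_shape, s, fem_cat,
                                frame = NULL, search_radius = search_radius)
    frame_s <- build_reference_frame(auto_f$coordinates["FMCP", ],
                                     auto_f$coordinates["FLCP", ])
    auto_t <- run_leave_one_out(annotations, corr$tibia$corresponded,
                                corr$tibia$mean_shape, s, tib_cat,
                                frame = frame_s,
                                search_radius = search_radius)
    autos[[s]] <- merge_landmarks(auto_f, auto_t)
    autos[[s]]$subject <- s
  }

  report <- run_validation(annotations, autos, catalog, ms_catalog)

  truth_lm <- do.call(rbind, lapply(names(cohort$subjects), function(s) {
    tl <- cohort$subjects[[s]]$truth$landmarks
    ac <- autos[[s]]$coordinates[rownames(tl), , drop = FALSE]
    data.frame(subject = s, item = rownames(tl),
               error = sqrt(rowSums((ac - tl)^2)))
  }))
  rownames(truth_lm) <- NULL
  truth_ms <- do.call(rbind, lapply(names(cohort$subjects), function(s) {
    tm <- cohort$subjects[[s]]$truth$measurements
    am <- measure_all(autos[[s]], ms_catalog,
                      cohort$subjects[[s]]$truth$frame)
    data.frame(subject = s, item = am$abbreviation,
               error = abs(am$value_mm - tm[am$abbreviation]))
  }))
  rownames(truth_ms) <- NULL

  structure(list(
    report = report,
    truth_landmark_errors = truth_lm,
    truth_measurement_errors = truth_ms,
    autos = autos,
    annotations = annotations,
    cohort = cohort,
    correspondence = lapply(corr, `[[`, "residuals")
  ), class = "phantom_rehearsal")
}
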