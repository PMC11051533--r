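#' Euclidean landmark errors against the mode's ground truth
#'
#' Three comparison designs share one error definition (Euclidean distance
#' to a mean ground truth):
#' \describe{
#'   \item{INTRA}{repeats of a single observer; truth = mean of the repeats.}
#'   \item{INTER}{one (repeat-averaged) set per observer; truth = mean across
#'     observers. Observers with repeats are pre-averaged so every observer
#'     carries equal weight.}
#'   \item{METHOD}{the automated set against the expert mean of the manual
#'     observations.}
#' }
#'
#' @param observations list of [landmark_set()] objects (manual annotations
#'   of one subject).
#' @param mode "INTRA", "INTER" or "METHOD".
#' @param auto the automated [landmark_set()] (METHOD mode only).
#' @return data.frame: subject, item (acronym), comparison, observer,
#'   repeat, error (mm).
#' @export
landmark_errors <- function(observations, mode = c("INTRA", "INTER", "METHOD"),
                            auto = NULL) {
  mode <- match.arg(mode)
  if (mode == "INTRA") {
    obs_ids <- unique(vapply(observations, `[[`, "", "observer"))
    if (length(obs_ids) != 1L) {
      stop("INTRA mode expects repeats of a single observer")
    }
    if (length(observations) < 2L) stop("INTRA mode needs >= 2 repeats")
    truth <- expert_mean_landmarks(observations)
    sets <- observations
  } else if (mode == "INTER") {
    by_obs <- split(observations, vapply(observations, `[[`, "", "observer"))
    if (length(by_obs) < 2L) stop("INTER mode needs >= 2 observers")
    truth <- expert_mean_landmarks(observations)
    sets <- lapply(by_obs, function(ss) {
      m <- expert_mean_landmarks(ss)
      m$observer <- ss[[1]]$observer
      m
    })
  } else {
    if (is.null(auto)) stop("METHOD mode needs the automated landmark set")
    truth <- expert_mean_landmarks(observations)
    sets <- list(auto)
  }
  acr <- rownames(truth$coordinates)
  out <- do.call(rbind, lapply(sets, function(s) {
    d <- s$coordinates[acr, , drop = FALSE] - truth$coordinates
    data.frame(subject = s$subject, item = acr, comparison = mode,
               observer = s$observer, "repeat" = s$repeat_id,
               error = sqrt(rowSums(d^2)), check.names = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Absolute measurement errors against the mode's ground truth
#'
#' Same designs as [landmark_errors()], with absolute scalar differences of
#' measurement values instead of Euclidean distances.
#'
#' @param measurements data.frame of measurement rows (subject, observer,
#'   repeat, abbreviation, value_mm) for one subject; manual rows for
#'   INTRA/INTER, manual rows plus `auto` for METHOD.
#' @param mode "INTRA", "INTER" or "METHOD".
#' @param auto data.frame of automated measurement rows (METHOD mode).
#' @return data.frame: subject, item (abbreviation), comparison, observer,
#'   repeat, error (mm).
#' @export
measurement_errors <- function(measurements,
                               mode = c("INTRA", "INTER", "METHOD"),
                               auto = NULL) {
  mode <- match.arg(mode)
  if (mode == "INTRA") {
    if (length(unique(measurements$observer)) != 1L) {
      stop("INTRA mode expects repeats of a single observer")
    }
    if (length(unique(measurements$`repeat`)) < 2L) {
      stop("INTRA mode needs >= 2 repeats")
    }
    truth <- stats::aggregate(value_mm ~ abbreviation, measurements, mean)
    sets <- measurements
  } else if (mode == "INTER") {
    per_obs <- stats::aggregate(value_mm ~ abbreviation + observer + subject,
                                measurements, mean)
    if (length(unique(per_obs$observer)) < 2L) {
      stop("INTER mode needs >= 2 observers")
    }
    truth <- stats::aggregate(value_mm ~ abbreviation, per_obs, mean)
    sets <- per_obs
    sets$`repeat` <- 1L
  } else {
    if (is.null(auto)) stop("METHOD mode needs automated measurements")
    per_obs <- stats::aggregate(value_mm ~ abbreviation + observer + subject,
                                measurements, mean)
    truth <- stats::aggregate(value_mm ~ abbreviation, per_obs, mean)
    sets <- auto
    if (!"repeat" %in% names(sets)) sets$`repeat` <- 1L
  }
  tv <- stats::setNames(truth$value_mm, truth$abbreviation)
  out <- data.frame(subject = sets$subject, item = sets$abbreviation,
                    comparison = mode, observer = sets$observer,
                    "repeat" = sets$`repeat`,
                    error = abs(sets$value_mm - tv[sets$abbreviation]),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Quartile summary with the 1.5 IQR outlier rule
#'
#' Quartiles use linear interpolation of order statistics
#' (`stats::quantile` type 7). Observations outside
#' \eqn{[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]} are flagged as
#' outliers.
#'
#' @param samples numeric vector of errors, or a data.frame with an `error`
#'   column (as produced by [landmark_errors()]).
#' @return list of class `quartile_summary`: q1, median, q3, iqr,
#'   outlier_low, outlier_high, outlier_ids (indices into the input), mean,
#'   sd, n.
#' @export
quartile_summary <- function(samples) {
  err <- if (is.data.frame(samples)) samples$error else samples
  if (length(err) == 0L) stop("no samples")
  q <- stats::quantile(err, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  structure(list(
    q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
    outlier_low = lo, outlier_high = hi,
    outlier_ids = which(err < lo | err > hi),
    mean = mean(err), sd = stats::sd(err), n = length(err)
  ), class = "quartile_summary")
}

#' Intraclass correlation coefficient, absolute agreement, single rater
#'
#' Computes ICC(A,1) from the two-way ANOVA mean squares of a complete
#' subjects x raters table:
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject (row), \eqn{MS_C} the between-rater
#' (column), and \eqn{MS_E} the residual mean squares, for n subjects and k
#' raters. The two-way mixed (raters fixed, e.g. repeats of one observer)
#' and two-way random (raters sampled, e.g. different observers or methods)
#' models share this point estimate for absolute agreement; the choice is
#' carried as a label.
#'
#' @param table numeric matrix, subjects in rows, raters in columns, no
#'   missing cells; >= 2 subjects and >= 2 raters.
#' @param model "TWO_WAY_MIXED" or "TWO_WAY_RANDOM".
#' @return list of class `icc_result`: value, model,
#'   definition ("ABSOLUTE_AGREEMENT"), unit ("SINGLE_RATER"), n_subjects,
#'   n_raters, mean squares, and `degenerate` (TRUE when all cells are equal,
#'   in which case the ICC is reported as 1).
#' @export
icc <- function(table, model = c("TWO_WAY_MIXED", "TWO_WAY_RANDOM")) {
  model <- match.arg(model)
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("ICC table has missing cells")
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2L || k < 2L) stop("ICC needs >= 2 subjects and >= 2 raters")
  degenerate <- FALSE
  if (max(table) - min(table) == 0) {
    value <- 1
    degenerate <- TRUE
    msr <- msc <- mse <- 0
  } else {
    gm <- mean(table)
    rowm <- rowMeans(table)
    colm <- colMeans(table)
    ssr <- k * sum((rowm - gm)^2)
    ssc <- n * sum((colm - gm)^2)
    sse <- sum((table - outer(rowm, rep(1, k)) -
                  outer(rep(1, n), colm) + gm)^2)
    msr <- ssr / (n - 1)
    msc <- ssc / (k - 1)
    mse <- sse / ((n - 1) * (k - 1))
    value <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  structure(list(value = value, model = model,
                 definition = "ABSOLUTE_AGREEMENT", unit = "SINGLE_RATER",
                 n_subjects = n, n_raters = k,
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 degenerate = degenerate),
            class = "icc_result")
}

#' Bland-Altman agreement of two methods
#'
#' @param manual,auto paired numeric vectors (per-subject manual mean and
#'   automated values).
#' @return list of class `bland_altman`: per-subject `mean` and `diff`
#'   (auto - manual), `bias`, `sd_diff`, and limits of agreement
#'   `loa_low`/`loa_high` = bias -/+ 1.96 sd.
#' @export
bland_altman <- function(manual, auto) {
  if (length(manual) != length(auto)) stop("unpaired inputs")
  if (length(manual) < 2L) stop("Bland-Altman needs >= 2 pairs")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(mean = (manual + auto) / 2, diff = d, bias = bias,
                 sd_diff = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = length(d)),
            class = "bland_altman")
}

#' Success rate at tolerance (empirical CDF of errors)
#'
#' @param samples numeric errors or data.frame with an `error` column.
#' @param tolerances increasing positive tolerance grid (mm).
#' @param item label carried into the result.
#' @return list of class `success_curve`: item, tolerances, rates (fraction
#'   of samples with error <= tolerance).
#' @export
success_rates <- function(samples, tolerances, item = "all") {
  err <- if (is.data.frame(samples)) samples$error else samples
  if (length(err) == 0L) stop("no samples")
  if (any(tolerances <= 0)) stop("tolerances must be > 0")
  tolerances <- sort(tolerances)
  rates <- vapply(tolerances, function(t) mean(err <= t), numeric(1))
  structure(list(item = item, tolerances = tolerances, rates = rates),
            class = "success_curve")
}

#' Per-subject outlier counts
#'
#' Flags outliers per item (landmark or measurement) with the 1.5 IQR rule
#' of [quartile_summary()], then counts flagged samples per subject and
#' comparison mode.
#'
#' @param samples data.frame of error samples (columns subject, item,
#'   comparison, error).
#' @return data.frame: subject, comparison, n_outliers (zero rows included).
#' @export
outliers_per_subject <- function(samples) {
  samples$is_outlier <- FALSE
  for (grp in split(seq_len(nrow(samples)),
                    list(samples$item, samples$comparison), drop = TRUE)) {
    qs <- quartile_summary(samples$error[grp])
    samples$is_outlier[grp[qs$outlier_ids]] <- TRUE
  }
  agg <- stats::aggregate(is_outlier ~ subject + comparison, samples, sum)
  names(agg)[3] <- "n_outliers"
  agg[order(agg$comparison, agg$subject), , drop = FALSE]
}

#' Default tolerance grids for success-rate curves
#' @param what "landmarks" (0.5 to 6 mm by 0.5) or "measurements"
#'   (0.25 to 3 mm by 0.25).
#' @return numeric vector of tolerances (mm).
#' @export
default_tolerances <- function(what = c("landmarks", "measurements")) {
  what <- match.arg(what)
  if (what == "landmarks") seq(0.5, 6, by = 0.5) else seq(0.25, 3, by = 0.25)
}
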