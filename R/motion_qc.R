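#' Scrubbing configuration
#'
#' Defaults mirror the acquisition/QC regime the pipeline targets: discard
#' the first 5 volumes (signal equilibration), flag volumes whose RMS
#' successive intensity difference (DVARS) exceeds 1.5 interquartile ranges
#' above the 75th centile, retain the contiguous 1600-volume window with the
#' fewest flagged volumes, and exclude the subject entirely when more than
#' 10% of the retained window (160 of 1600 volumes) is flagged.
#'
#' @param n_discard_initial initial volumes to drop (default 5).
#' @param iqr_multiplier outlier threshold multiplier (default 1.5).
#' @param centile upper quartile used by the threshold, percent (default 75).
#' @param window_length retained window length in volumes (default 1600).
#' @param exclusion_fraction maximum tolerated outlier fraction in the
#'   window, exceeding it (strictly) excludes the subject (default 0.10).
#' @return a `scrub_config` list.
#' @export
scrub_config <- function(n_discard_initial = 5, iqr_multiplier = 1.5,
                         centile = 75, window_length = 1600,
                         exclusion_fraction = 0.10) {
  if (exclusion_fraction <= 0 || exclusion_fraction > 1)
    stop("exclusion_fraction must be in (0, 1]")
  structure(list(n_discard_initial = as.integer(n_discard_initial),
                 iqr_multiplier = iqr_multiplier, centile = centile,
                 window_length = as.integer(window_length),
                 exclusion_fraction = exclusion_fraction),
            class = "scrub_config")
}

#' DVARS: RMS successive-difference series
#'
#' `dvars[t] = sqrt(mean over channels of (x[t,] - x[t-1,])^2)` for t >= 2;
#' the first volume has no predecessor and its DVARS is defined as 0.
#' For ROI-level runs the channels are the ROI time-courses; for voxel-level
#' data, all voxels.
#'
#' @param data volumes x channels matrix.
#' @return numeric vector, one value per volume.
#' @export
compute_dvars <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 volumes to compute DVARS")
  d <- diff(data)
  c(0, sqrt(rowMeans(d^2)))
}

#' Flag motion-outlier volumes by the IQR rule
#'
#' A volume is a motion outlier when its DVARS exceeds
#' `Q75 + iqr_multiplier * (Q75 - Q25)`, quartiles taken over the DVARS
#' values of volumes 2..T (the undefined first value is excluded from the
#' distribution and never flagged). Quartiles use linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param run a `bold_run` (already cropped of initial volumes).
#' @param config a [scrub_config()].
#' @return list with `dvars`, `threshold` and logical `outlier_mask`.
#' @export
flag_motion_outliers <- function(run, config = scrub_config()) {
  stopifnot(inherits(run, "bold_run"))
  dv <- compute_dvars(run$data)
  q <- stats::quantile(dv[-1], probs = c(1 - config$centile / 100,
                                         config$centile / 100),
                       names = FALSE, type = 7)
  threshold <- q[2] + config$iqr_multiplier * (q[2] - q[1])
  mask <- dv > threshold
  mask[1] <- FALSE
  list(dvars = dv, threshold = threshold, outlier_mask = mask)
}

#' Best contiguous low-motion window
#'
#' Finds the start of the contiguous window of exactly `window_length`
#' volumes containing the minimum number of flagged volumes; ties are broken
#' by the smallest start index. Implemented as a sliding (cumulative) sum,
#' linear in the run length.
#'
#' @param outlier_mask logical vector, one element per volume.
#' @param window_length window length in volumes.
#' @return list with `window_start` (1-based index) and
#'   `n_outliers_in_window`.
#' @export
select_window <- function(outlier_mask, window_length) {
  n <- length(outlier_mask)
  window_length <- as.integer(window_length)
  if (window_length > n)
    stop("window_length (", window_length, ") exceeds mask length (", n, ")")
  cs <- c(0L, cumsum(as.integer(outlier_mask)))
  counts <- cs[(window_length + 1):(n + 1)] - cs[1:(n - window_length + 1)]
  start <- which.min(counts)  # which.min returns the first minimum
  list(window_start = start, n_outliers_in_window = counts[start])
}

#' Scrub a BOLD run: crop, flag, window, exclusion verdict
#'
#' Discards the initial volumes, identifies motion outliers on the remainder,
#' retains the best contiguous window, and labels the subject excluded when
#' the window contains strictly more than
#' `exclusion_fraction * window_length` flagged volumes. Flagged volumes
#' inside the retained window are kept in the series (the retained sample is
#' continuous; the count is used only for the exclusion verdict). The
#' per-subject motion summary (later usable as a covariate) is the outlier
#' count in the window.
#'
#' @param run a `bold_run`.
#' @param config a [scrub_config()].
#' @return list with `run` (the windowed `bold_run`, `qc_state`
#'   `"scrubbed"`) and `report` (a `motion_qc_report`).
#' @export
apply_scrub <- function(run, config = scrub_config()) {
  stopifnot(inherits(run, "bold_run"))
  n <- nrow(run$data)
  needed <- config$n_discard_initial + config$window_length
  if (n < needed)
    stop("run has ", n, " volumes; scrubbing needs at least ", needed)
  data <- run$data[(config$n_discard_initial + 1):n, , drop = FALSE]
  cropped <- bold_run(data, subject_id = run$subject_id, group = run$group,
                      repetition_time_s = run$repetition_time_s,
                      channel_kind = run$channel_kind, qc_state = "cropped")
  fl <- flag_motion_outliers(cropped, config)
  w <- select_window(fl$outlier_mask, config$window_length)
  excluded <- w$n_outliers_in_window >
    config$exclusion_fraction * config$window_length
  idx <- w$window_start:(w$window_start + config$window_length - 1)
  windowed <- bold_run(data[idx, , drop = FALSE],
                       subject_id = run$subject_id, group = run$group,
                       repetition_time_s = run$repetition_time_s,
                       channel_kind = run$channel_kind,
                       qc_state = "scrubbed")
  report <- structure(list(
    subject_id = run$subject_id,
    dvars = fl$dvars,
    threshold = fl$threshold,
    outlier_mask = fl$outlier_mask,
    window_start = w$window_start,
    window_length = config$window_length,
    n_outliers_in_window = w$n_outliers_in_window,
    excluded = excluded,
    motion_summary = w$n_outliers_in_window
  ), class = "motion_qc_report")
  list(run = windowed, report = report)
}

#' @export
print.motion_qc_report <- function(x, ...) {
  cat(sprintf(paste0("<motion_qc_report> %s: %d/%d volumes flagged, window ",
                     "[%d, %d] with %d outliers, %s\n"),
              x$subject_id, sum(x$outlier_mask), length(x$outlier_mask),
              x$window_start, x$window_start + x$window_length - 1,
              x$n_outliers_in_window,
              if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}

#' Write a motion QC report to JSON
#'
#' Serializes the report (DVARS series, threshold, mask, window, verdict) as
#' JSON; the outlier mask can additionally be written as a one-column text
#' file of 0/1 values.
#'
#' @param report a `motion_qc_report`.
#' @param path output JSON path.
#' @param mask_path optional path for the one-column mask file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path, mask_path = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(mask_path))
    utils::write.table(as.integer(report$outlier_mask), mask_path,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
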