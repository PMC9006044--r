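#' Extract sphere-ROI mean time-courses from a 4D volume
#'
#' For each template ROI, averages (unweighted) the time-courses of all
#' voxels whose centre — 0-based voxel indices mapped through the affine to
#' mm coordinates — lies at Euclidean distance `<= radius` from the ROI
#' centre. Column order follows template order.
#'
#' @param volume either a list with elements `data` (4D array, x,y,z,t) and
#'   `affine` (4x4 voxel-index-to-mm matrix), or an `RNifti` image (the
#'   sform/qform affine is used).
#' @param template an ROI template.
#' @param subject_id,group metadata for the returned run.
#' @param repetition_time_s repetition time of the run.
#' @return a `bold_run` of kind `"roi"` with one column per template ROI.
#' @export
extract_roi_timecourses <- function(volume, template,
                                    subject_id = "sub-01", group = "unknown",
                                    repetition_time_s = 0.392) {
  validate_roi_template(template, warn_overlap = FALSE)
  if (inherits(volume, "niftiImage")) {
    affine <- RNifti::xform(volume)
    data <- as.array(volume)
  } else {
    affine <- volume$affine
    data <- volume$data
  }
  if (length(dim(data)) != 4) stop("expected a 4D volume (x, y, z, t)")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("volume affine is not invertible")
  dims <- dim(data)
  n_t <- dims[4]
  # mm coordinates of every voxel centre along each axis (affine is applied
  # to the full index grid; handles any invertible affine)
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  mm <- idx %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(idx), 3, byrow = TRUE)
  out <- matrix(NA_real_, n_t, nrow(template))
  colnames(out) <- template$name
  flat <- matrix(data, prod(dims[1:3]), n_t)
  for (r in seq_len(nrow(template))) {
    d2 <- (mm[, 1] - template$x[r])^2 + (mm[, 2] - template$y[r])^2 +
      (mm[, 3] - template$z[r])^2
    members <- which(d2 <= template$radius[r]^2)
    if (length(members) == 0)
      stop("ROI sphere contains no voxel centre: ", template$name[r])
    out[, r] <- if (length(members) == 1) flat[members, ] else
      colMeans(flat[members, , drop = FALSE])
  }
  bold_run(out, subject_id = subject_id, group = group,
           repetition_time_s = repetition_time_s, channel_kind = "roi",
           qc_state = "raw")
}

#' Zero-phase temporal low-pass filter
#'
#' Applies a 5th-order Butterworth low-pass filter forward and backward
#' (zero phase, so correlations between channels are not distorted by filter
#' lag). Startup transients are controlled by odd-reflection padding before
#' each pass; the padded segment is discarded, so output length equals input
#' length and the channel mean is preserved to numerical tolerance. As with
#' any finite-length zero-phase filter, residual edge effects of the order
#' of the endpoint signal values can remain within the filter's settling
#' span (roughly the pad length, 300 samples) of the run boundaries; the
#' interior of a scrubbed 1600-volume window is unaffected.
#'
#' @param run a `bold_run`.
#' @param cutoff_hz low-pass cutoff in Hz (default 0.08); must be below the
#'   Nyquist frequency `1 / (2 * TR)`.
#' @param order Butterworth order (default 5).
#' @return the filtered `bold_run` (`qc_state` `"filtered"`).
#' @export
lowpass_filter <- function(run, cutoff_hz = 0.08, order = 5) {
  stopifnot(inherits(run, "bold_run"))
  nyquist <- 1 / (2 * run$repetition_time_s)
  if (cutoff_hz >= nyquist)
    stop(sprintf("cutoff %.3f Hz is not below the Nyquist frequency %.3f Hz",
                 cutoff_hz, nyquist))
  n <- nrow(run$data)
  pad <- min(n - 1L, 300L)
  if (pad < 3 * (order + 1))
    stop("run too short for stable zero-phase filtering (", n, " volumes)")
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  filt1 <- function(x) {
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    yf <- signal::filter(bf, c(left, x, right))
    y <- rev(signal::filter(bf, rev(yf)))
    y[(pad + 1):(pad + n)]
  }
  out <- apply(run$data, 2, filt1)
  colnames(out) <- colnames(run$data)
  bold_run(out, subject_id = run$subject_id, group = run$group,
           repetition_time_s = run$repetition_time_s,
           channel_kind = run$channel_kind, qc_state = "filtered",
           spike_at = run$spike_at)
}

#' Read and write BOLD runs
#'
#' ROI-level runs are stored as tab-delimited text: one row per volume, one
#' column per ROI, header row of ROI names, preceded by comment lines
#' (`# key=value`) carrying subject id, group, repetition time and QC state.
#' The round-trip is lossless to full double precision. Volumetric runs are
#' NIfTI-1 (`.nii` / `.nii.gz`), read and written through RNifti, which
#' honours the affine and data-scaling header fields.
#'
#' @param path file path; format is chosen by extension (`.nii`/`.nii.gz`
#'   for NIfTI, anything else is ROI-matrix text).
#' @param run a `bold_run` (for writing).
#' @return `read_run` returns a `bold_run`; `write_run` returns `path`
#'   invisibly.
#' @export
read_run <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4) pd[4] else 0.392
    return(structure(list(data = as.array(img),
                          affine = matrix(as.numeric(RNifti::xform(img)),
                                          4, 4),
                          repetition_time_s = tr),
                     class = "bold_volume"))
  }
  lines <- readLines(path, n = 50)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list(subject_id = "sub-01", group = "unknown",
               repetition_time_s = 0.392, qc_state = "raw")
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta))
      meta[[kv[1]]] <- if (kv[1] == "repetition_time_s")
        as.numeric(kv[2]) else kv[2]
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  bold_run(as.matrix(tab), subject_id = meta$subject_id, group = meta$group,
           repetition_time_s = meta$repetition_time_s,
           qc_state = meta$qc_state)
}

#' @rdname read_run
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id=%s", run$subject_id),
               sprintf("# group=%s", run$group),
               sprintf("# repetition_time_s=%.17g", run$repetition_time_s),
               sprintf("# qc_state=%s", run$qc_state)), con)
  utils::write.table(format(run$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a volumetric run as NIfTI-1
#'
#' @param volume list with `data` (4D array) and `affine` (4x4), e.g. from
#'   [render_volumetric_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param repetition_time_s repetition time stored in the header.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, repetition_time_s = 0.392) {
  img <- RNifti::asNifti(volume$data)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::pixdim(img) <- c(rep(abs(volume$affine[1, 1]), 3),
                           repetition_time_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}
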