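#' Target correlation structure for a synthetic group
#'
#' A covariance spec fixes the block structure of the 19x19 channel
#' correlation matrix used to simulate a group's BOLD runs: one within-network
#' correlation per network, a common baseline between-network correlation, and
#' a separate override for the DMN-DAN pairing so the characteristic
#' default-mode / dorsal-attention decoupling can be injected (or withheld).
#'
#' @param r_within_dmn,r_within_dan,r_within_ecn target Pearson correlation
#'   between channels of the same network, in (-1, 1).
#' @param r_between baseline correlation between channels of different
#'   networks.
#' @param r_dmn_dan correlation for DMN-DAN channel pairs; defaults to
#'   `r_between` (no selective decoupling).
#' @param variance stationary channel variance (signal units squared).
#' @return a `covariance_spec` list.
#' @export
covariance_spec <- function(r_within_dmn, r_within_dan, r_within_ecn,
                            r_between, r_dmn_dan = r_between, variance = 1) {
  r <- c(r_within_dmn, r_within_dan, r_within_ecn, r_between, r_dmn_dan)
  if (!all(is.finite(r)) || any(abs(r) >= 1))
    stop("all correlation targets must lie strictly inside (-1, 1)")
  if (!is.finite(variance) || variance <= 0)
    stop("variance must be positive")
  structure(list(r_within_dmn = r_within_dmn, r_within_dan = r_within_dan,
                 r_within_ecn = r_within_ecn, r_between = r_between,
                 r_dmn_dan = r_dmn_dan, variance = variance),
            class = "covariance_spec")
}

#' Built-in group profiles for the synthetic cohort generator
#'
#' Correlation profiles emulating the qualitative group contrasts the
#' pipeline is designed to detect. Values are generator choices, not
#' measurements (no usable effect sizes are published for these contrasts):
#'
#' * `"term"` - all three networks cohesive (within > between) with the
#'   DMN-DAN pairing selectively reduced below baseline: the full-term
#'   pattern (three distinct networks, reciprocal relationship present).
#' * `"preterm_tea"` - the same structure attenuated: preterm at
#'   term-equivalent age (networks present but weaker).
#' * `"preterm_pre_tea"` - only the DAN block elevated; DMN and ECN at
#'   baseline and no DMN-DAN reduction: before term-equivalent age.
#' * `"adult"` - strong blocks and a mildly anticorrelated DMN-DAN pairing.
#' * `"null"` - no block structure at all (every correlation at baseline);
#'   used for type-I error control checks.
#'
#' @param profile one of `"term"`, `"preterm_tea"`, `"preterm_pre_tea"`,
#'   `"adult"`, `"null"`.
#' @return a [covariance_spec()].
#' @export
group_profile <- function(profile = c("term", "preterm_tea",
                                      "preterm_pre_tea", "adult", "null")) {
  profile <- match.arg(profile)
  switch(profile,
    term = covariance_spec(0.30, 0.35, 0.25, r_between = 0.10,
                           r_dmn_dan = 0.02),
    preterm_tea = covariance_spec(0.22, 0.28, 0.18, r_between = 0.10,
                                  r_dmn_dan = 0.04),
    preterm_pre_tea = covariance_spec(0.10, 0.35, 0.10, r_between = 0.10,
                                      r_dmn_dan = 0.10),
    adult = covariance_spec(0.50, 0.55, 0.45, r_between = 0.10,
                            r_dmn_dan = -0.05),
    null = covariance_spec(0.10, 0.10, 0.10, r_between = 0.10)
  )
}

#' Build the block correlation matrix implied by a covariance spec
#'
#' Entry (i, j) is the within value of the shared network when ROIs i and j
#' belong to the same network, `r_dmn_dan` when one is DMN and the other DAN,
#' and `r_between` otherwise; the diagonal is exactly 1. The requested block
#' matrix can be slightly indefinite; negative eigenvalues are clipped to
#' 1e-10 and the matrix renormalized to unit diagonal. If the repair moves
#' any entry by more than 0.05 from the request the spec is considered
#' unrealizable and the call fails, reporting the smallest eigenvalue.
#'
#' @param spec a [covariance_spec()].
#' @param template an ROI template (supplies network labels; needs >= 2
#'   networks).
#' @return a symmetric positive semi-definite correlation matrix with ROI
#'   names as dimnames.
#' @export
build_network_covariance <- function(spec, template = default_roi_template()) {
  stopifnot(inherits(spec, "covariance_spec"))
  validate_roi_template(template, warn_overlap = FALSE)
  net <- template$network
  n <- length(net)
  within <- c(DMN = spec$r_within_dmn, DAN = spec$r_within_dan,
              ECN = spec$r_within_ecn)
  R <- matrix(spec$r_between, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (net[i] == net[j]) {
        R[i, j] <- within[[net[i]]]
      } else if ((net[i] == "DMN" && net[j] == "DAN") ||
                 (net[i] == "DAN" && net[j] == "DMN")) {
        R[i, j] <- spec$r_dmn_dan
      }
    }
  }
  diag(R) <- 1
  eg <- eigen(R, symmetric = TRUE)
  min_eig <- min(eg$values)
  if (min_eig < 0) {
    vals <- pmax(eg$values, 1e-10)
    R2 <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    diag(R2) <- 1
    if (max(abs(R2 - R)) > 0.05)
      stop(sprintf(paste0("requested block correlation matrix is not ",
                          "positive semi-definite (smallest eigenvalue ",
                          "%.4g) and cannot be repaired within 0.05"),
                   min_eig))
    R <- (R2 + t(R2)) / 2
  }
  dimnames(R) <- list(template$name, template$name)
  R
}

#' Motion-spike specification
#'
#' Spikes emulate motion-corrupted volumes: a global additive offset applied
#' to every channel of the affected volume, expressed in multiples of the
#' stationary channel standard deviation — exactly the kind of artifact an
#' RMS successive-difference (DVARS) metric detects.
#'
#' @param n_spikes number of corrupted volumes (ignored when `at` is given).
#' @param amplitude offset in multiples of channel SD (default 10).
#' @param at optional explicit volume indices (1-based); otherwise placement
#'   is uniform at random without replacement.
#' @return a `spike_spec` list.
#' @export
spike_spec <- function(n_spikes = 0, amplitude = 10, at = NULL) {
  if (!is.null(at)) n_spikes <- length(at)
  if (n_spikes < 0) stop("n_spikes must be non-negative")
  structure(list(n_spikes = as.integer(n_spikes), amplitude = amplitude,
                 at = if (is.null(at)) NULL else as.integer(at)),
            class = "spike_spec")
}

#' Simulate one ROI-level BOLD run
#'
#' Channels follow a first-order autoregression `x[t] = phi * x[t-1] + e[t]`
#' with Gaussian innovations whose correlation matrix is `cov` (all channels
#' share `phi`, so stationary cross-correlations equal the innovation
#' correlations). The series is initialized from its stationary distribution.
#' Spike volumes receive a global additive offset of
#' `amplitude * stationary SD` on every channel.
#'
#' @param cov target correlation matrix (e.g. from
#'   [build_network_covariance()]).
#' @param n_volumes run length in volumes.
#' @param repetition_time_s repetition time in seconds (default 0.392).
#' @param ar_coefficient AR(1) coefficient in `[0, 1)` (default 0.3).
#' @param spikes a [spike_spec()] or NULL.
#' @param seed integer seed; the run is a deterministic function of it.
#' @param variance stationary channel variance.
#' @param subject_id,group metadata carried on the run.
#' @return a `bold_run`: list with `data` (volumes x channels matrix),
#'   `subject_id`, `group`, `repetition_time_s`, `channel_kind = "roi"`,
#'   `qc_state = "raw"` and `spike_at` (the realized spike indices).
#' @export
simulate_roi_run <- function(cov, n_volumes, repetition_time_s = 0.392,
                             ar_coefficient = 0.3, spikes = NULL, seed = 1,
                             variance = 1, subject_id = "sub-01",
                             group = "synthetic") {
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must be in [0, 1)")
  p <- nrow(cov)
  eg_min <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (eg_min < -1e-8) stop("cov must be positive semi-definite")
  set.seed(seed)
  L <- chol(cov + diag(1e-12, p))
  innov_sd <- sqrt(variance * (1 - ar_coefficient^2))
  E <- matrix(stats::rnorm(n_volumes * p), n_volumes, p) %*% L * innov_sd
  # stationary start: inflate the first innovation to the stationary scale
  E[1, ] <- E[1, ] / sqrt(1 - ar_coefficient^2)
  X <- apply(E, 2, function(e)
    as.numeric(stats::filter(e, ar_coefficient, method = "recursive")))
  spike_at <- integer(0)
  if (!is.null(spikes) && spikes$n_spikes > 0) {
    spike_at <- if (!is.null(spikes$at)) spikes$at else
      sort(sample.int(n_volumes, spikes$n_spikes))
    if (any(spike_at < 1 | spike_at > n_volumes))
      stop("spike indices fall outside the run (length ", n_volumes, ")")
    X[spike_at, ] <- X[spike_at, ] + spikes$amplitude * sqrt(variance)
  }
  colnames(X) <- rownames(cov)
  bold_run(X, subject_id = subject_id, group = group,
           repetition_time_s = repetition_time_s, spike_at = spike_at)
}

#' Construct a BOLD run object
#'
#' @param data volumes x channels numeric matrix (no missing values).
#' @param subject_id,group identifiers.
#' @param repetition_time_s repetition time, seconds (> 0).
#' @param channel_kind `"roi"` or `"voxel"`.
#' @param qc_state free-text QC state tag (`"raw"`, `"scrubbed"`,
#'   `"filtered"`).
#' @param spike_at optional known spike indices (ground truth annotation).
#' @return a `bold_run` list.
#' @export
bold_run <- function(data, subject_id = "sub-01", group = "unknown",
                     repetition_time_s = 0.392, channel_kind = "roi",
                     qc_state = "raw", spike_at = integer(0)) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("BOLD run contains missing values")
  if (!is.numeric(repetition_time_s) || repetition_time_s <= 0)
    stop("repetition_time_s must be positive")
  structure(list(data = data, subject_id = subject_id, group = group,
                 repetition_time_s = repetition_time_s,
                 channel_kind = channel_kind, qc_state = qc_state,
                 spike_at = as.integer(spike_at)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s (%s): %d volumes x %d channels, TR %.3f s, qc=%s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$repetition_time_s, x$qc_state))
  invisible(x)
}

#' Cohort specification for the synthetic generator
#'
#' @param groups named list; each element a list with `n_subjects`,
#'   `covariance` (a [covariance_spec()]) and optionally `spikes`
#'   (a [spike_spec()] applied to every subject of the group).
#' @param n_volumes volumes per run (default 2300, matching the acquisition
#'   the scrubbing defaults are calibrated to).
#' @param repetition_time_s repetition time (default 0.392 s).
#' @param ar_coefficient AR(1) coefficient (default 0.3).
#' @param seed integer master seed; fully determines the cohort.
#' @param template ROI template.
#' @param age optional per-subject annotation data frame (e.g. gestational
#'   age at birth / postmenstrual age at scan, weeks); carried through
#'   untouched, consumed by no operation.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(groups, n_volumes = 2300, repetition_time_s = 0.392,
                        ar_coefficient = 0.3, seed = 1,
                        template = default_roi_template(), age = NULL) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  if (anyDuplicated(names(groups))) stop("duplicate group labels")
  structure(list(groups = groups, n_volumes = as.integer(n_volumes),
                 repetition_time_s = repetition_time_s,
                 ar_coefficient = ar_coefficient, seed = as.integer(seed),
                 template = template, age = age),
            class = "cohort_spec")
}

#' Simulate a multi-subject cohort
#'
#' One run per subject, ids `<group>_<i>`. Each subject's run is generated
#' under a seed derived deterministically from the master seed, and the
#' returned truth record (master seed, per-group specs, realized per-subject
#' spike indices and seeds) is sufficient to regenerate the cohort
#' bit-exactly via `simulate_cohort` on the same spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `runs` (list of `bold_run`) and `truth` (a
#'   `truth_record`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  runs <- list()
  truth_subjects <- list()
  subj_counter <- 0L
  for (g in names(spec$groups)) {
    grp <- spec$groups[[g]]
    n_sub <- grp$n_subjects
    if (is.null(n_sub)) stop("group '", g, "' lacks n_subjects")
    if (n_sub == 0) next
    cov <- build_network_covariance(grp$covariance, spec$template)
    for (i in seq_len(n_sub)) {
      subj_counter <- subj_counter + 1L
      sid <- sprintf("%s_%02d", g, i)
      if (sid %in% names(runs)) stop("duplicate subject id: ", sid)
      sseed <- (spec$seed + 7919L * subj_counter) %% .Machine$integer.max
      run <- simulate_roi_run(
        cov, n_volumes = spec$n_volumes,
        repetition_time_s = spec$repetition_time_s,
        ar_coefficient = spec$ar_coefficient,
        spikes = grp$spikes, seed = sseed,
        variance = grp$covariance$variance,
        subject_id = sid, group = g)
      runs[[sid]] <- run
      truth_subjects[[sid]] <- list(group = g, seed = sseed,
                                    spike_at = run$spike_at)
    }
  }
  truth <- structure(list(
    seed = spec$seed,
    groups = lapply(spec$groups, function(grp)
      unclass(grp$covariance)),
    subjects = truth_subjects
  ), class = "truth_record")
  list(runs = runs, truth = truth)
}

#' Render an ROI-level run into a 4D volume
#'
#' Places every ROI sphere on a regular voxel grid: voxels whose centre lies
#' within a sphere carry that ROI's time-course plus independent Gaussian
#' noise; all other voxels carry noise only. The affine maps 0-based voxel
#' indices to the template's mm space (RAS+, axis-aligned, isotropic
#' spacing). Used to exercise sphere extraction end-to-end.
#'
#' @param run an ROI-level `bold_run` whose channels match the template rows.
#' @param template ROI template with pairwise non-overlapping spheres
#'   (overlap is an error naming the offending pair).
#' @param spacing_mm isotropic voxel size (default 2.15 mm).
#' @param noise_sd background/measurement noise SD (default 0).
#' @param margin_mm padding around the bounding box of the spheres.
#' @param seed seed for the noise field.
#' @return list with `data` (4D array x,y,z,t) and `affine` (4x4).
#' @export
render_volumetric_run <- function(run, template, spacing_mm = 2.15,
                                  noise_sd = 0, margin_mm = 4, seed = 1) {
  stopifnot(inherits(run, "bold_run"))
  validate_roi_template(template, warn_overlap = FALSE)
  ov <- overlapping_roi_pairs(template)
  if (nrow(ov) > 0)
    stop("cannot render overlapping ROI spheres: ",
         ov$a[1], " / ", ov$b[1])
  if (ncol(run$data) != nrow(template))
    stop("run channel count does not match template")
  lo <- c(min(template$x - template$radius), min(template$y - template$radius),
          min(template$z - template$radius)) - margin_mm
  hi <- c(max(template$x + template$radius), max(template$y + template$radius),
          max(template$z + template$radius)) + margin_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing_mm)) + 1L)
  affine <- diag(c(spacing_mm, spacing_mm, spacing_mm, 1))
  affine[1:3, 4] <- lo
  n_t <- nrow(run$data)
  set.seed(seed)
  vol <- array(if (noise_sd > 0)
    stats::rnorm(prod(dims) * n_t, sd = noise_sd) else 0,
    dim = c(dims, n_t))
  centers_x <- lo[1] + (seq_len(dims[1]) - 1) * spacing_mm
  centers_y <- lo[2] + (seq_len(dims[2]) - 1) * spacing_mm
  centers_z <- lo[3] + (seq_len(dims[3]) - 1) * spacing_mm
  for (r in seq_len(nrow(template))) {
    dx2 <- (centers_x - template$x[r])^2
    dy2 <- (centers_y - template$y[r])^2
    dz2 <- (centers_z - template$z[r])^2
    in_r <- which(outer(outer(dx2, dy2, "+"), dz2, "+") <=
                    template$radius[r]^2, arr.ind = TRUE)
    if (nrow(in_r) == 0)
      stop("ROI sphere contains no voxel centre: ", template$name[r])
    for (k in seq_len(nrow(in_r))) {
      vol[in_r[k, 1], in_r[k, 2], in_r[k, 3], ] <-
        vol[in_r[k, 1], in_r[k, 2], in_r[k, 3], ] + run$data[, r]
    }
  }
  list(data = vol, affine = affine)
}
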