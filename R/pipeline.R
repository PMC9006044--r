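#' One-call synthetic cohort under a named group profile
#'
#' Convenience constructor: simulates `n_subjects` runs under one of the
#' built-in [group_profile()] correlation structures and returns the runs
#' together with the ground-truth record.
#'
#' @param profile profile name (see [group_profile()]).
#' @param n_subjects subjects to simulate.
#' @param n_volumes volumes per run (default 400; the full-length default
#'   of [cohort_spec()] is 2300).
#' @param seed master seed.
#' @param spikes optional [spike_spec()] applied to every subject.
#' @param template ROI template.
#' @param ar_coefficient AR(1) coefficient (default 0.3).
#' @return list with `runs` and `truth` (see [simulate_cohort()]).
#' @export
simulate_profile_cohort <- function(profile, n_subjects, n_volumes = 400,
                                    seed = 1, spikes = NULL,
                                    template = default_roi_template(),
                                    ar_coefficient = 0.3) {
  groups <- list(list(n_subjects = n_subjects,
                      covariance = group_profile(profile),
                      spikes = spikes))
  names(groups) <- profile
  simulate_cohort(cohort_spec(groups, n_volumes = n_volumes, seed = seed,
                              template = template,
                              ar_coefficient = ar_coefficient))
}

#' Cohort-level verdicts from simulated or real runs
#'
#' Computes subject-level FC, network summaries and the two headline
#' verdicts (per-network distinctness; DMN-DAN reciprocal relationship) for
#' a list of ROI-level runs.
#'
#' @param runs list of `bold_run`s.
#' @param template ROI template.
#' @param alpha significance level (default 0.05).
#' @return list with `summaries`, `distinct` (named logical), `reciprocal`
#'   (logical) and the full `report`.
#' @export
cohort_verdicts <- function(runs, template = default_roi_template(),
                            alpha = 0.05) {
  summaries <- summarize_cohort(runs, template)
  rep <- verdict_report(summaries, alpha)
  list(summaries = summaries,
       distinct = rep$distinctness$distinct,
       reciprocal = rep$reciprocal$reciprocal,
       report = rep)
}
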