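tpl <- default_roi_template()

test_that("block covariance construction honours the spec entries", {
  id_spec <- covariance_spec(0, 0, 0, r_between = 0)
  # all-zero off-diagonal request collapses to the identity
  expect_equal(build_network_covariance(id_spec, tpl),
               diag(19), ignore_attr = TRUE)

  spec <- covariance_spec(0.5, 0.5, 0.5, r_between = 0.1, r_dmn_dan = -0.1)
  R <- build_network_covariance(spec, tpl)
  expect_identical(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 19))
  dmn <- which(tpl$network == "DMN"); dan <- which(tpl$network == "DAN")
  ecn <- which(tpl$network == "ECN")
  expect_true(all(R[dmn, dan] == -0.1))
  expect_true(all(R[dmn, ecn] == 0.1))
  win <- R[dmn, dmn]
  expect_true(all(win[upper.tri(win)] == 0.5))
  # PSD verified by eigendecomposition
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("unrealizably indefinite requests fail, naming the eigenvalue", {
  bad <- covariance_spec(0.9, 0.9, 0.9, r_between = -0.9)
  expect_error(build_network_covariance(bad, tpl),
               "smallest eigenvalue")
})

test_that("simulated runs are deterministic in the seed and match the
           requested correlation structure", {
  a <- simulate_roi_run(diag(19), 500, seed = 42)
  b <- simulate_roi_run(diag(19), 500, seed = 42)
  expect_identical(a$data, b$data)
  c <- simulate_roi_run(diag(19), 500, seed = 43)
  expect_false(identical(a$data, c$data))

  # Monte-Carlo check against the specified covariance: white channels
  big <- simulate_roi_run(diag(19), 20000, ar_coefficient = 0, seed = 7)
  R <- cor(big$data)
  expect_lt(max(abs(R[upper.tri(R)])), 0.03)

  # block structure recovered on average under AR(1) noise
  spec <- group_profile("term")
  cov <- build_network_covariance(spec, tpl)
  run <- simulate_roi_run(cov, 20000, ar_coefficient = 0.3, seed = 8)
  Rhat <- cor(run$data)
  expect_lt(mean(abs(Rhat[upper.tri(Rhat)] - cov[upper.tri(cov)])), 0.01)
})

test_that("spike volumes dominate the successive-difference series", {
  cov <- build_network_covariance(group_profile("null"), tpl)
  run <- simulate_roi_run(cov, 1000, spikes = spike_spec(at = c(100, 200)),
                          seed = 5)
  dv <- compute_dvars(run$data)
  top4 <- order(dv, decreasing = TRUE)[1:4]
  expect_setequal(top4, c(100, 101, 200, 201))
  expect_error(simulate_roi_run(cov, 50, spikes = spike_spec(at = 60)),
               "outside the run")
})

test_that("cohorts are reproducible from their spec, sensitive to the seed,
           and tolerate empty groups", {
  groups <- list(
    term = list(n_subjects = 3, covariance = group_profile("term")),
    pre = list(n_subjects = 0, covariance = group_profile("preterm_pre_tea")))
  sp <- cohort_spec(groups, n_volumes = 120, seed = 11)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(lapply(c1$runs, `[[`, "data"),
                   lapply(c2$runs, `[[`, "data"))
  expect_equal(length(c1$runs), 3)
  expect_equal(c1$truth$seed, 11L)

  sp2 <- cohort_spec(groups, n_volumes = 120, seed = 12)
  c3 <- simulate_cohort(sp2)
  expect_false(identical(c1$runs[[1]]$data, c3$runs[[1]]$data))

  expect_error(cohort_spec(list(a = list(), a = list())), "duplicate")
})

test_that("truth record carries per-subject spike ground truth", {
  groups <- list(g = list(n_subjects = 2,
                          covariance = group_profile("null"),
                          spikes = spike_spec(n_spikes = 4)))
  cc <- simulate_cohort(cohort_spec(groups, n_volumes = 200, seed = 3))
  for (sid in names(cc$runs))
    expect_identical(cc$truth$subjects[[sid]]$spike_at,
                     cc$runs[[sid]]$spike_at)
})

test_that("cohort-level exclusion arithmetic: 10 corrupted pairs out of 47
           leaves 37 usable pairs", {
  # 47 subjects with two scans each; scan 2 of the first 10 subjects is
  # saturated with motion spikes so that every candidate window is over the
  # 10% outlier budget.
  cfg <- scrub_config(window_length = 400)
  n_vol <- 600
  cov <- build_network_covariance(group_profile("term"), tpl)
  # evenly spaced spikes: every 400-volume window holds > 40 outliers (10%),
  # while keeping the contaminated share of the DVARS distribution low
  # enough that the IQR threshold still sits in the clean bulk
  heavy <- spike_spec(at = seq(8, 592, by = 13), amplitude = 10)
  kept_pairs <- 0
  for (s in 1:47) {
    scan1 <- simulate_roi_run(cov, n_vol, seed = 1000 + s)
    spikes2 <- if (s <= 10) heavy else NULL
    scan2 <- simulate_roi_run(cov, n_vol, spikes = spikes2, seed = 2000 + s)
    ok1 <- !apply_scrub(scan1, cfg)$report$excluded
    ok2 <- !apply_scrub(scan2, cfg)$report$excluded
    if (ok1 && ok2) kept_pairs <- kept_pairs + 1
  }
  expect_equal(kept_pairs, 37)
})

test_that("volumetric rendering refuses overlapping spheres and matches a
           brute-force voxel scan", {
  run <- constant_spike_run(3, integer(0), n_channels = 19)
  run$data[] <- seq_len(length(run$data))
  expect_error(render_volumetric_run(run, default_roi_template()),
               "overlapping")

  # single 8-mm sphere at the origin on a 2-mm grid: voxel membership count
  # equals an exhaustive scan over all voxel centres
  one <- default_roi_template()[c(1, 7, 15), ]
  one$x <- c(0, 40, 80); one$y <- 0; one$z <- 0
  class(one) <- c("roi_template", "data.frame")
  small <- bold_run(matrix(rnorm(9), 3, 3), repetition_time_s = 0.392)
  vol <- render_volumetric_run(small, one, spacing_mm = 2, seed = 2)
  dims <- dim(vol$data)[1:3]
  count_inside <- 0
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
    for (k in 0:(dims[3] - 1)) {
      mm <- vol$affine %*% c(i, j, k, 1)
      if (sum((mm[1:3] - c(0, 0, 0))^2) <= 64) count_inside <- count_inside + 1
    }
  # voxels carrying ROI 1's series (noise is zero, so exact equality)
  flat <- matrix(vol$data, prod(dims), 3)
  roi1 <- sum(apply(flat, 1, function(v) all(v == small$data[, 1])))
  expect_equal(roi1, count_inside)
})
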