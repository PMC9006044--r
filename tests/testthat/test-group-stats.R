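test_that("a 2-level repeated-measures factor reproduces the paired t-test", {
  set.seed(10)
  for (trial in 1:50) {
    n <- sample(5:30, 1)
    Y <- matrix(rnorm(2 * n, sd = runif(1, 0.5, 2)), n, 2)
    an <- rm_anova(Y, within = data.frame(cond = c("a", "b")))
    tt <- t_test(Y[, 1], Y[, 2], kind = "paired")
    expect_equal(an$F, tt$t^2, tolerance = 1e-10)
    expect_equal(an$p_raw, tt$p_raw, tolerance = 1e-10)
    expect_equal(an$epsilon, 1)
    expect_equal(an$df1, 1)
    expect_equal(an$df2, n - 1)
  }
})

test_that("one-way F and Greenhouse-Geisser epsilon match a from-scratch
           matrix computation", {
  # fixed 6-subject x 3-condition toy table
  Y <- matrix(c(3.1, 4.0, 5.2,
                2.7, 3.1, 4.9,
                4.2, 4.4, 6.0,
                3.3, 3.0, 4.1,
                2.9, 4.2, 5.5,
                3.8, 3.7, 4.8), 6, 3, byrow = TRUE)
  an <- rm_anova(Y, within = data.frame(cond = c("c1", "c2", "c3")))
  or <- oneway_rm_oracle(Y)
  expect_equal(an$F, or$F, tolerance = 1e-12)
  expect_equal(an$epsilon, or$epsilon, tolerance = 1e-12)
  expect_equal(an$df1, or$epsilon * or$df1, tolerance = 1e-12)
  expect_equal(an$df2, or$epsilon * or$df2, tolerance = 1e-12)
  expect_equal(an$p_raw,
               pf(or$F, or$epsilon * or$df1, or$epsilon * or$df2,
                  lower.tail = FALSE), tolerance = 1e-12)
})

test_that("two-way within F statistics agree with aov's decomposition", {
  set.seed(11)
  n <- 12
  Y <- matrix(rnorm(6 * n), n, 6) +
    matrix(rep(c(0.5, 0, -0.2, 0.1, 0.8, 0), each = n), n, 6)
  design <- data.frame(fc_type = rep(c("within", "between"), each = 3),
                       network = rep(c("DMN", "DAN", "ECN"), 2))
  an <- rm_anova(Y, design)
  long <- data.frame(
    y = as.vector(Y),
    subj = factor(rep(seq_len(n), 6)),
    fc_type = factor(rep(design$fc_type, each = n)),
    network = factor(rep(design$network, each = n)))
  fit <- summary(aov(y ~ fc_type * network +
                       Error(subj / (fc_type * network)), data = long))
  get_f <- function(stratum, row)
    fit[[stratum]][[1]][row, "F value"]
  expect_equal(an$F[an$effect == "fc_type"],
               get_f("Error: subj:fc_type", "fc_type"), tolerance = 1e-8)
  expect_equal(an$F[an$effect == "network"],
               get_f("Error: subj:network", "network"), tolerance = 1e-8)
  expect_equal(an$F[an$effect == "fc_type:network"],
               get_f("Error: subj:fc_type:network", "fc_type:network"),
               tolerance = 1e-8)
  # uncorrected dfs recoverable from corrected ones via epsilon
  i <- an$effect == "fc_type:network"
  expect_equal(an$df1[i] / an$epsilon[i], 2)
  expect_equal(an$df2[i] / an$epsilon[i], 2 * (n - 1))
})

test_that("epsilon respects its bounds and approaches 1 under sphericity", {
  set.seed(12)
  for (trial in 1:200) {
    k <- sample(3:5, 1)
    n <- sample(6:15, 1)
    Y <- matrix(rnorm(k * n), n, k)
    an <- rm_anova(Y, within = data.frame(cond = paste0("c", 1:k)))
    expect_gte(an$epsilon, 1 / (k - 1))
    expect_lte(an$epsilon, 1)
  }
  # compound symmetry (subject effect + iid noise) satisfies sphericity
  n <- 500
  Y <- matrix(rnorm(n), n, 3) + matrix(rnorm(3 * n), n, 3)
  an <- rm_anova(Y, within = data.frame(cond = c("a", "b", "c")))
  expect_gt(an$epsilon, 0.95)
})

test_that("t tests match the closed form and reject degenerate input", {
  a <- c(5.1, 4.8, 6.0, 5.7, 4.9, 5.3, 6.1, 5.0, 5.6, 5.2)
  b <- c(4.6, 4.9, 5.1, 5.4, 4.2, 5.0, 5.5, 4.7, 5.1, 4.8)
  d <- a - b
  tt <- t_test(a, b, "paired")
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  expect_equal(tt$df, 9)
  expect_equal(tt$mean_diff, mean(d))

  expect_error(t_test(a, a, "paired"), "zero variance")
  expect_error(t_test(b + 1, b, "paired"), "zero variance")
  ti <- t_test(a, b, "independent")
  expect_equal(ti$df, 18)
})

test_that("motion-adjusted group GLM nests the t-test and partials out a
           mediating covariate", {
  set.seed(13)
  g <- rep(c("neonate", "adult"), each = 20)
  y <- rnorm(40) + (g == "neonate") * 0.8
  res <- glm_group_covariate(y, g, motion = rep(0, 40))
  ti <- t_test(y[g == "adult"], y[g == "neonate"], "independent")
  expect_equal(res$F, ti$t^2, tolerance = 1e-10)
  expect_true(is.na(res$covariate_coef))

  # group effect entirely mediated by motion: group F collapses
  motion <- rnorm(40, mean = (g == "neonate") * 3, sd = 0.3)
  y2 <- motion + rnorm(40, sd = 0.2)
  res2 <- glm_group_covariate(y2, g, motion)
  expect_gt(res2$p_raw, 0.05)
  naive <- t_test(y2[g == "adult"], y2[g == "neonate"], "independent")
  expect_lt(naive$p_raw, 1e-6)

  # coefficients equal the normal-equations solution on a fixed toy table
  yv <- c(2.3, 1.9, 3.0, 2.8, 4.1, 4.4, 3.9, 4.6)
  gv <- rep(c("a", "b"), each = 4)
  mv <- c(0.2, 0.5, 0.1, 0.9, 1.4, 1.1, 1.8, 1.2)
  fit <- glm_group_covariate(yv, gv, mv)
  X <- cbind(1, gv == "b", mv)
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  expect_equal(fit$covariate_coef, beta[3], tolerance = 1e-10)
  expect_error(glm_group_covariate(yv, gv, as.numeric(gv == "b")),
               "collinear")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.04), 1), c(0.2, 0.04))
  expect_error(bonferroni(0.1, 0), ">= 1")
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
})

test_that("display centering removes subject means, keeps condition means", {
  Y <- matrix(c(1, 2,
                4, 6,
                2, 5), 3, 2, byrow = TRUE)
  adj <- center_for_display(Y)
  expect_equal(colMeans(adj), colMeans(Y))
  expect_equal(adj, Y - rowMeans(Y) + mean(Y))
  one <- center_for_display(matrix(c(3, 9, 6), 3, 1))
  expect_equal(as.vector(one), rep(6, 3))
})

test_that("verdicts recover the generating structure of each profile", {
  term <- simulate_profile_cohort("term", 40, n_volumes = 400, seed = 101)
  vt <- cohort_verdicts(term$runs)
  expect_true(all(vt$distinct))
  expect_true(vt$reciprocal)

  pre <- simulate_profile_cohort("preterm_pre_tea", 40, n_volumes = 400,
                                 seed = 102)
  vp <- cohort_verdicts(pre$runs)
  expect_true(vp$distinct[["DAN"]])
  expect_false(vp$distinct[["DMN"]])
  expect_false(vp$distinct[["ECN"]])
  expect_false(vp$reciprocal)

  null <- simulate_profile_cohort("null", 40, n_volumes = 400, seed = 103)
  vn <- cohort_verdicts(null$runs)
  expect_false(any(vn$distinct))
  expect_false(vn$reciprocal)
})

test_that("the reciprocal verdict is directional: significant ANOVA with the
           wrong pairing lowest stays false", {
  set.seed(15)
  n <- 40
  s <- data.frame(
    subject = paste0("s", 1:n), group = "toy",
    between_DMN_DAN = 0.10 + rnorm(n, sd = 0.02),
    between_DMN_ECN = 0.02 + rnorm(n, sd = 0.02),
    between_DAN_ECN = 0.10 + rnorm(n, sd = 0.02))
  r <- reciprocal_relationship(s)
  expect_lt(r$anova$p_corrected[1], 0.05)
  expect_false(r$reciprocal)
})
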