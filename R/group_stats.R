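#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully-within, balanced repeated-measures ANOVA on a subjects x conditions
#' table. Each effect (main effects and all interactions) is computed from
#' orthonormal contrast scores: with contrast matrix `K` (conditions x q,
#' orthonormal columns spanning the effect), scores `D = Y K` give
#' `F = (n * sum(colMeans(D)^2) / q) / (tr(S) / q)` with `S` the sample
#' covariance of the scores, numerator df `q` and denominator df `q (n - 1)`.
#' For effects involving a within-factor with three or more levels the
#' Greenhouse-Geisser epsilon `tr(S)^2 / (q * tr(S S))` multiplies both
#' degrees of freedom (possibly non-integer) before the p-value is taken
#' from the F distribution; two-level effects keep integer dfs and
#' `epsilon = 1`. Epsilon is bounded in `[1/q, 1]`.
#'
#' @param y subjects x conditions numeric matrix (complete; no missing
#'   cells).
#' @param within data frame with one row per column of `y`; each column a
#'   factor describing that condition's level on one within-subject factor.
#' @param m Bonferroni family size applied to the (GG-corrected) p-values
#'   (default 1, i.e. no correction).
#' @return data frame with one row per effect: `effect`, `F`, `df1`, `df2`
#'   (corrected, possibly non-integer), `epsilon`, `p_raw`, `p_corrected`.
#' @export
rm_anova <- function(y, within, m = 1) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing cells in repeated-measures table")
  n <- nrow(y)
  within <- as.data.frame(within)
  within[] <- lapply(within, function(f) factor(f))
  levs <- lapply(within, levels)
  ks <- vapply(levs, length, 1L)
  if (prod(ks) != ncol(y) || nrow(within) != ncol(y))
    stop("factor structure does not match the number of conditions")
  if (n < 3) stop("need at least 3 subjects")
  # reorder columns into standard factorial order (first factor fastest)
  std <- do.call(expand.grid, levs)
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  ord <- match(key(std), key(within))
  if (anyNA(ord)) stop("conditions do not form a complete factorial design")
  y <- y[, ord, drop = FALSE]

  ortho_contrasts <- function(k) {
    cn <- stats::contr.helmert(k)
    cn %*% diag(1 / sqrt(colSums(cn^2)), ncol(cn), ncol(cn))
  }
  fnames <- names(within)
  nfac <- length(fnames)
  effects <- unlist(lapply(seq_len(nfac), function(sz)
    utils::combn(nfac, sz, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    K <- matrix(1, 1, 1)
    for (i in seq_len(nfac)) {  # Kronecker in expand.grid order
      Ci <- if (i %in% eff) ortho_contrasts(ks[i]) else
        matrix(1 / sqrt(ks[i]), ks[i], 1)
      K <- Ci %x% K
    }
    q <- ncol(K)
    D <- y %*% K
    mbar <- colMeans(D)
    S <- stats::cov(D)
    ss_eff <- n * sum(mbar^2)
    ss_err <- (n - 1) * sum(diag(S))
    if (ss_err <= 0) stop("zero error variance for effect ",
                          paste(fnames[eff], collapse = ":"))
    Fval <- (ss_eff / q) / (ss_err / (q * (n - 1)))
    needs_gg <- any(ks[eff] >= 3)
    eps <- if (needs_gg) {
      e <- sum(diag(S))^2 / (q * sum(S * S))
      min(1, max(1 / q, e))
    } else 1
    df1 <- eps * q
    df2 <- eps * q * (n - 1)
    p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
    data.frame(effect = paste(fnames[eff], collapse = ":"),
               F = Fval, df1 = df1, df2 = df2, epsilon = eps,
               p_raw = p, p_corrected = bonferroni(p, m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired and independent t-tests
#'
#' Thin wrapper around [stats::t.test()] (independent tests use the pooled
#' two-sample form, df `n1 + n2 - 2`) returning the fields the pipeline
#' reports, with an explicit Bonferroni family size.
#'
#' @param a,b numeric vectors (equal length for paired tests).
#' @param kind `"paired"` or `"independent"`.
#' @param m Bonferroni family size (default 1).
#' @return data frame row: `kind`, `t`, `df`, `mean_diff`, `p_raw`,
#'   `p_corrected`.
#' @export
t_test <- function(a, b, kind = c("paired", "independent"), m = 1) {
  kind <- match.arg(kind)
  paired <- kind == "paired"
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    if (stats::sd(a - b) == 0)
      stop("zero variance of paired differences; t statistic undefined")
  } else if (length(a) < 2 || length(b) < 2) {
    stop("independent samples need n >= 2 per group")
  }
  tt <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = !paired),
    error = function(e) stop("degenerate t-test input: ",
                             conditionMessage(e)))
  p <- tt$p.value
  data.frame(kind = kind, t = unname(tt$statistic),
             df = unname(tt$parameter),
             mean_diff = if (paired) mean(a - b) else mean(a) - mean(b),
             p_raw = p, p_corrected = bonferroni(p, m),
             stringsAsFactors = FALSE)
}

#' Group comparison adjusted for head motion
#'
#' Least-squares fit of `value ~ intercept + group + motion` for a two-level
#' group factor, reporting the partial F for group (equal to the squared t
#' of the group coefficient) and the motion-covariate coefficient. A
#' zero-variance covariate is dropped, reducing the test to the pooled
#' independent t-test.
#'
#' @param values numeric outcome per subject.
#' @param group two-level factor (or coercible).
#' @param motion numeric per-subject motion summary (e.g. outlier count in
#'   the retained window).
#' @param m Bonferroni family size (default 1).
#' @return data frame row: `F`, `df1`, `df2`, `p_raw`, `p_corrected`,
#'   `covariate_coef`.
#' @export
glm_group_covariate <- function(values, group, motion, m = 1) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (length(values) != length(group) || length(motion) != length(group))
    stop("values, group and motion must have equal length")
  if (stats::sd(motion) == 0) {
    fit <- stats::lm(values ~ group)
    reduced <- stats::lm(values ~ 1)
    cov_coef <- NA_real_
  } else {
    fit <- stats::lm(values ~ group + motion)
    if (anyNA(stats::coef(fit)))
      stop("group indicator is collinear with the motion covariate")
    reduced <- stats::lm(values ~ motion)
    cov_coef <- unname(stats::coef(fit)["motion"])
  }
  an <- stats::anova(reduced, fit)
  Fval <- an$F[2]
  p <- an$`Pr(>F)`[2]
  data.frame(F = Fval, df1 = an$Df[2], df2 = an$Res.Df[2],
             p_raw = p, p_corrected = bonferroni(p, m),
             covariate_coef = cov_coef, stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` elementwise. The family size is always an explicit
#' argument; it is never inferred from the length of `p`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param m family size (>= 1, >= `length(p)` when correcting a whole
#'   family at once).
#' @return corrected p-values.
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("Bonferroni family size must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Remove inter-subject variability for display
#'
#' Subtracts each subject's mean across conditions and adds back the grand
#' mean, leaving condition means untouched. Used only for plotting
#' within-subject effects; never for inference.
#'
#' @param values subjects x conditions numeric matrix (complete).
#' @return adjusted matrix of the same shape.
#' @export
center_for_display <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells")
  values - rowMeans(values) + mean(values)
}

#' Network distinctness verdicts
#'
#' For each network, a paired t-test of within-network FC against that
#' network's pooled between-network FC across subjects. The network is
#' declared distinct (a cohesive unit differentiated from the other
#' networks) when the Bonferroni-corrected p (family = 3 networks) is below
#' `alpha` *and* the mean within-minus-between difference is positive.
#'
#' @param summaries cohort summary data frame from [summarize_cohort()].
#' @param alpha significance level (default 0.05).
#' @param m Bonferroni family size (default 3, the three networks).
#' @return list with `distinct` (named logical) and `tests` (data frame,
#'   one row per network).
#' @export
network_distinctness <- function(summaries, alpha = 0.05, m = 3) {
  if (nrow(summaries) < 3) stop("need at least 3 subjects")
  nets <- c("DMN", "DAN", "ECN")
  tests <- do.call(rbind, lapply(nets, function(nm) {
    tt <- t_test(summaries[[paste0("within_", nm)]],
                 summaries[[paste0("betweenall_", nm)]],
                 kind = "paired", m = m)
    cbind(network = nm, tt)
  }))
  distinct <- tests$p_corrected < alpha & tests$mean_diff > 0
  names(distinct) <- nets
  list(distinct = distinct, tests = tests)
}

#' Reciprocal-relationship verdict
#'
#' Tests the operational marker of the default-mode / dorsal-attention
#' decoupling: a one-way repeated-measures ANOVA (Greenhouse-Geisser
#' corrected) over the three between-network pairings (DMN-DAN, DMN-ECN,
#' DAN-ECN), followed by the two paired contrasts of DMN-DAN against each
#' other pairing (Bonferroni family = 2). The verdict is true when the
#' ANOVA is significant and both contrasts are significant with DMN-DAN
#' *lower* (negative mean difference).
#'
#' @param summaries cohort summary data frame.
#' @param alpha significance level (default 0.05).
#' @return list with `reciprocal` (logical), `anova` (one-row data frame)
#'   and `contrasts` (two-row data frame).
#' @export
reciprocal_relationship <- function(summaries, alpha = 0.05) {
  if (nrow(summaries) < 3) stop("need at least 3 subjects")
  Y <- as.matrix(summaries[, c("between_DMN_DAN", "between_DMN_ECN",
                               "between_DAN_ECN")])
  an <- rm_anova(Y, within = data.frame(pairing = colnames(Y)))
  c1 <- t_test(Y[, 1], Y[, 2], kind = "paired", m = 2)
  c2 <- t_test(Y[, 1], Y[, 3], kind = "paired", m = 2)
  contrasts <- rbind(cbind(contrast = "DMN-DAN vs DMN-ECN", c1),
                     cbind(contrast = "DMN-DAN vs DAN-ECN", c2))
  verdict <- an$p_corrected[1] < alpha &&
    all(contrasts$p_corrected < alpha) && all(contrasts$mean_diff < 0)
  list(reciprocal = verdict, anova = an, contrasts = contrasts)
}

#' Combined verdict report for a cohort
#'
#' Convenience wrapper producing both headline verdicts from a cohort
#' summary table, plus the 2x3 (FC type x network) repeated-measures ANOVA
#' over the within / pooled-between levels of the three networks.
#'
#' @param summaries cohort summary data frame.
#' @param alpha significance level.
#' @return list with `distinctness`, `reciprocal` and `anova_2x3`.
#' @export
verdict_report <- function(summaries, alpha = 0.05) {
  Y <- as.matrix(summaries[, c("within_DMN", "within_DAN", "within_ECN",
                               "betweenall_DMN", "betweenall_DAN",
                               "betweenall_ECN")])
  design <- data.frame(
    fc_type = rep(c("within", "between"), each = 3),
    network = rep(c("DMN", "DAN", "ECN"), 2))
  list(distinctness = network_distinctness(summaries, alpha),
       reciprocal = reciprocal_relationship(summaries, alpha),
       anova_2x3 = rm_anova(Y, design))
}
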