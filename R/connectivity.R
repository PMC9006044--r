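#' Subject-level functional connectivity matrix
#'
#' Computes the Pearson correlation between every pair of ROI time-courses
#' and applies the Fisher-z transform, `z = atanh(r)`. The diagonal is
#' stored as 0 and excluded from every downstream summary.
#'
#' @param run an ROI-level `bold_run` with at least 3 volumes and no
#'   constant channel.
#' @return an `fc_matrix`: a symmetric numeric matrix with attributes
#'   `subject_id`, `group` and `normalized` (FALSE).
#' @export
fc_matrix <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  X <- run$data
  if (nrow(X) < 3) stop("need at least 3 volumes to estimate correlations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant channel(s): ", paste(bad, collapse = ", "))
  }
  R <- stats::cor(X)
  off <- abs(R[upper.tri(R)])
  if (any(off >= 1))
    stop("degenerate input: perfectly (anti)correlated channel pair")
  Z <- atanh(R)
  diag(Z) <- 0
  structure(Z, subject_id = run$subject_id, group = run$group,
            normalized = FALSE, class = c("fc_matrix", "matrix", "array"))
}

#' Within-subject normalization of an FC matrix
#'
#' Z-scores the 171 unique off-diagonal Fisher-z entries against their
#' within-subject mean and standard deviation, so that between-group
#' comparisons reflect connectivity *patterns* rather than overall
#' connectivity strength. Symmetry is preserved; the diagonal stays 0.
#'
#' @param fc an un-normalized `fc_matrix`.
#' @param sd_type `"population"` (n denominator, the default) or `"sample"`
#'   (n - 1 denominator).
#' @return the normalized `fc_matrix` (attribute `normalized` TRUE).
#' @export
normalize_within_subject <- function(fc, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(fc, "fc_matrix"))
  if (isTRUE(attr(fc, "normalized")))
    stop("FC matrix is already normalized")
  up <- upper.tri(fc)
  v <- fc[up]
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (sd_type == "sample") s <- stats::sd(v)
  if (s == 0) stop("zero variance across FC entries; cannot normalize")
  out <- fc
  out[up] <- (v - m) / s
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  attr(out, "normalized") <- TRUE
  out
}

#' Network-level FC summary for one subject
#'
#' Averages the unique off-diagonal Fisher-z entries over the three
#' within-network pair sets (for the default 6/8/5 template: 15 DMN, 28 DAN,
#' 10 ECN pairs) and the three between-network pair sets (48 DMN-DAN,
#' 30 DMN-ECN, 40 DAN-ECN pairs). The per-network "between, overall" level
#' used as the between-network condition of the two-way ANOVA pools, by
#' default, all pairs with exactly one node in the network (so the two
#' pairings are weighted by their pair counts); `between = "mean_of_pairings"`
#' instead averages the two pairing means.
#'
#' @param fc an `fc_matrix`.
#' @param template the ROI template defining the networks.
#' @param between pooling rule for the per-network between-network level.
#' @return a one-row data frame with columns `subject`, `group`,
#'   `within_DMN`, `within_DAN`, `within_ECN`, `between_DMN_DAN`,
#'   `between_DMN_ECN`, `between_DAN_ECN`, `betweenall_DMN`,
#'   `betweenall_DAN`, `betweenall_ECN`.
#' @export
summarize_networks <- function(fc, template = default_roi_template(),
                               between = c("pooled", "mean_of_pairings")) {
  between <- match.arg(between)
  stopifnot(inherits(fc, "fc_matrix"))
  if (nrow(fc) != nrow(template))
    stop("FC matrix dimension does not match template")
  net <- template$network
  counts <- table(net)
  if (any(counts < 2)) stop("every network needs at least 2 nodes")
  pair_mean <- function(rows, cols) {
    sub <- fc[rows, cols, drop = FALSE]
    if (identical(rows, cols)) mean(sub[upper.tri(sub)]) else mean(sub)
  }
  idx <- split(seq_len(nrow(template)), net)
  w <- c(DMN = pair_mean(idx$DMN, idx$DMN),
         DAN = pair_mean(idx$DAN, idx$DAN),
         ECN = pair_mean(idx$ECN, idx$ECN))
  b <- c(`DMN_DAN` = pair_mean(idx$DMN, idx$DAN),
         `DMN_ECN` = pair_mean(idx$DMN, idx$ECN),
         `DAN_ECN` = pair_mean(idx$DAN, idx$ECN))
  pool <- function(n1) {
    others <- setdiff(c("DMN", "DAN", "ECN"), n1)
    if (between == "pooled") {
      vals <- c(as.vector(fc[idx[[n1]], idx[[others[1]]]]),
                as.vector(fc[idx[[n1]], idx[[others[2]]]]))
      mean(vals)
    } else {
      mean(c(pair_mean(idx[[n1]], idx[[others[1]]]),
             pair_mean(idx[[n1]], idx[[others[2]]])))
    }
  }
  data.frame(subject = attr(fc, "subject_id") %||% "sub-01",
             group = attr(fc, "group") %||% "unknown",
             within_DMN = w[["DMN"]], within_DAN = w[["DAN"]],
             within_ECN = w[["ECN"]],
             between_DMN_DAN = b[["DMN_DAN"]],
             between_DMN_ECN = b[["DMN_ECN"]],
             between_DAN_ECN = b[["DAN_ECN"]],
             betweenall_DMN = pool("DMN"),
             betweenall_DAN = pool("DAN"),
             betweenall_ECN = pool("ECN"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Network summaries for a whole cohort
#'
#' Runs [fc_matrix()] (optionally followed by [normalize_within_subject()])
#' and [summarize_networks()] on every run and stacks the results.
#'
#' @param runs list of ROI-level `bold_run`s.
#' @param template ROI template.
#' @param normalize normalize each FC matrix within subject first
#'   (default FALSE; the within-group verdict procedures use raw Fisher-z,
#'   normalization is for between-group pattern comparisons).
#' @param between pooling rule passed to [summarize_networks()].
#' @return a data frame with one row per subject.
#' @export
summarize_cohort <- function(runs, template = default_roi_template(),
                             normalize = FALSE,
                             between = c("pooled", "mean_of_pairings")) {
  between <- match.arg(between)
  rows <- lapply(runs, function(r) {
    fc <- fc_matrix(r)
    if (normalize) fc <- normalize_within_subject(fc)
    summarize_networks(fc, template, between = between)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an FC matrix / long-format summaries
#'
#' FC matrices are written as square tab-delimited text with ROI names as
#' header and row names; summaries as a long-format CSV with columns
#' `subject,group,measure,network_or_pair,value`.
#'
#' @param fc an `fc_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fc, path) {
  utils::write.table(format(unclass(fc), digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = rownames(fc) %||% FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @param summaries a cohort summary data frame from [summarize_cohort()].
#' @export
write_summaries <- function(summaries, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(summaries)), function(i) {
    row <- summaries[i, ]
    vals <- names(row)[!(names(row) %in% c("subject", "group"))]
    data.frame(subject = row$subject, group = row$group,
               measure = sub("_.*$", "", vals),
               network_or_pair = sub("^[a-z]+_", "", vals),
               value = as.numeric(row[vals]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
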