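#' Node dissimilarities from group FC
#'
#' Averages the supplied (normalized) FC matrices into a group matrix and
#' computes, for every node pair (i, j), one minus the Pearson correlation
#' between rows i and j after excluding the two self-entries (columns i and
#' j) pairwise. Identical connectivity profiles give distance 0, perfectly
#' opposite profiles give 2.
#'
#' @param fc a single `fc_matrix`, or a list of them (averaged entrywise).
#' @return a symmetric, zero-diagonal, non-negative distance matrix.
#' @export
node_distances <- function(fc) {
  M <- if (is.list(fc) && !is.matrix(fc))
    Reduce(`+`, lapply(fc, unclass)) / length(fc) else unclass(fc)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      keep <- setdiff(seq_len(n), c(i, j))
      a <- M[i, keep]; b <- M[j, keep]
      if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("constant connectivity profile for node ",
             (rownames(M) %||% seq_len(n))[if (stats::sd(a) == 0) i else j])
      D[i, j] <- D[j, i] <- 1 - stats::cor(a, b)
    }
  }
  D
}

#' Agglomerative clustering of network nodes
#'
#' Average-linkage (UPGMA) hierarchical clustering of the node distance
#' matrix (other linkages available), cut at `k` clusters. The dendrogram
#' can be exported as Newick text via [write_dendrogram()].
#'
#' @param d symmetric distance matrix (e.g. from [node_distances()]).
#' @param k number of clusters, between 1 and the number of nodes.
#' @param method linkage passed to [stats::hclust()] (default
#'   `"average"`; `"complete"`, `"single"`, `"ward.D2"` also supported).
#' @return list with `labels` (named integer cluster assignment), `tree`
#'   (the `hclust` object) and `heights` (merge heights).
#' @export
hierarchical_cluster <- function(d, k, method = "average") {
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  hc <- stats::hclust(stats::as.dist(d), method = method)
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, tree = hc, heights = hc$height)
}

#' @rdname hierarchical_cluster
#' @param tree an `hclust` object.
#' @param path output path for the Newick text.
#' @export
write_dendrogram <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds the nodes in `dims` dimensions preserving the rank order of the
#' dissimilarities. Disparities are fitted by monotone (isotonic) regression
#' of the configuration distances on the dissimilarity ranks; the
#' configuration is updated by the Guttman transform, and an update is only
#' accepted if it does not increase stress-1
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, so the recorded stress sequence is
#' non-increasing. The first start is the classical (metric) MDS solution of
#' the rank-transformed dissimilarities; additional restarts (controlled by
#' `seed`) use random configurations and the best final stress wins. Every
#' step — initialization included — depends on the input only through its
#' ranks, so the result is invariant to monotone transforms of the
#' dissimilarities.
#'
#' @param d symmetric dissimilarity matrix.
#' @param dims embedding dimension (default 2).
#' @param seed integer seed for random restarts.
#' @param n_restarts number of starts (default 4; the first is classical
#'   MDS).
#' @param max_iter iteration cap per start (default 500); hitting it is
#'   reported via `converged = FALSE`, not an error.
#' @param tol stop when the stress decrease falls below this (default 1e-9).
#' @return list with `points` (nodes x dims), `stress` (final stress-1),
#'   `stress_trace` (per-iteration stress of the winning start),
#'   `iterations`, `converged` and `seed`.
#' @export
nmds_embed <- function(d, dims = 2, seed = 1, n_restarts = 4,
                       max_iter = 500, tol = 1e-9) {
  d <- as.matrix(d)
  n <- nrow(d)
  low <- lower.tri(d)
  delta <- d[low]
  if (all(delta == 0)) stop("all dissimilarities are zero")
  set.seed(seed)
  denom_ord <- order(delta)

  run_one <- function(X) {
    trace <- numeric(0)
    stress_of <- function(X) {
      dv <- as.vector(stats::dist(X))
      dhat <- numeric(length(dv))
      o <- denom_ord
      dhat[o] <- stats::isoreg(dv[o])$yf
      s2 <- sum(dv^2)
      list(stress = sqrt(sum((dv - dhat)^2) / s2), dv = dv, dhat = dhat)
    }
    st <- stress_of(X)
    trace <- st$stress
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      Dm <- matrix(0, n, n); Dh <- matrix(0, n, n)
      Dm[low] <- st$dv; Dm <- Dm + t(Dm)
      Dh[low] <- st$dhat; Dh <- Dh + t(Dh)
      ratio <- ifelse(Dm > 0, Dh / Dm, 0)
      B <- -ratio
      diag(B) <- rowSums(ratio)
      Xn <- B %*% X / n
      stn <- stress_of(Xn)
      if (stn$stress > st$stress) break  # never accept an increase
      dec <- st$stress - stn$stress
      X <- Xn; st <- stn
      trace <- c(trace, st$stress)
      if (dec < tol) { converged <- TRUE; break }
    }
    list(points = X, stress = st$stress, stress_trace = trace,
         iterations = it, converged = converged || it < max_iter)
  }

  rank_d <- matrix(0, n, n)
  rank_d[low] <- rank(delta)
  rank_d <- rank_d + t(rank_d)
  init_classical <- stats::cmdscale(rank_d, k = dims)
  if (ncol(init_classical) < dims)
    init_classical <- cbind(init_classical,
                            matrix(0, n, dims - ncol(init_classical)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    X0 <- if (r == 1) init_classical else
      matrix(stats::rnorm(n * dims, sd = stats::sd(rank(delta)) + 1e-12),
             n, dims)
    res <- run_one(X0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  rownames(best$points) <- rownames(d)
  c(best, list(seed = seed))
}

#' Cluster purity against network identity
#'
#' The fraction of nodes belonging to the majority network of their cluster:
#' the sum over clusters of the majority-network count, divided by the
#' number of nodes. Equals 1 when clusters coincide with networks; a single
#' all-node cluster scores the share of the largest network (8/19 for the
#' default template).
#'
#' @param labels cluster assignment, one per node, in template order.
#' @param template the ROI template supplying network identity.
#' @return purity score in `[0, 1]`.
#' @export
cluster_purity <- function(labels, template = default_roi_template()) {
  if (length(labels) != nrow(template))
    stop("labels must cover all template nodes")
  tab <- table(labels, template$network)
  sum(apply(tab, 1, max)) / nrow(template)
}
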