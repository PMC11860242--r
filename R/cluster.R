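# Reduce a panel of traits to genetically independent representatives:
# pick the highly intercorrelated subset, Ward-cluster it on d = 1 - |rg|,
# choose the cluster count by the elbow rule, and represent each cluster by
# the trait most aligned with the cluster's first principal component.

#' Traits highly genetically correlated with at least one other
#'
#' @param rg symmetric genetic-correlation matrix with unit diagonal.
#' @param threshold absolute-correlation threshold (default 0.80).
#' @return Character vector (or integer indices when unlabelled) of traits
#'   with at least one off-diagonal `|rg| > threshold`.
#' @export
high_corr_subset <- function(rg, threshold = 0.80) {
  check_corr_matrix(rg)
  A <- abs(rg)
  diag(A) <- 0
  hit <- apply(A, 1, max) > threshold
  if (!is.null(rownames(rg))) rownames(rg)[hit] else which(hit)
}

check_corr_matrix <- function(rg) {
  if (!is.matrix(rg) || nrow(rg) != ncol(rg))
    stop("rg must be a square matrix")
  if (!isSymmetric(unname(rg), tol = 1e-8))
    stop("rg must be symmetric")
  if (any(abs(diag(rg) - 1) > 1e-8))
    stop("rg must have unit diagonal")
  invisible(rg)
}

#' Ward clustering of a genetic-correlation submatrix
#'
#' Agglomerative hierarchical clustering with Ward linkage on the distance
#' `d = 1 - |rg|` (absolute value, because both strongly positive and
#' strongly negative correlations indicate shared architecture).
#'
#' @param rg symmetric correlation (sub)matrix, >= 2 traits.
#' @return An `hclust` dendrogram.
#' @export
ward_cluster <- function(rg) {
  check_corr_matrix(rg)
  stopifnot(nrow(rg) >= 2)
  d <- stats::as.dist(1 - abs(rg))
  out <- stats::hclust(d, method = "ward.D2")
  # all input distances equal => no real structure; recorded for the elbow
  attr(out, "degenerate_input") <-
    (max(d) - min(d)) < 1e-12 * max(max(d), 1)
  out
}

#' Choose the cluster count by the elbow rule
#'
#' The within-cluster dispersion profile of a Ward dendrogram grows by the
#' merge height each time two clusters fuse, so its second difference with
#' respect to k equals the gap between consecutive merge heights; the elbow
#' is the k with the largest such gap (ties broken towards smaller k).
#' A degenerate structure -- all pairwise distances equal, so every k is as
#' good as any other -- returns `k = 1` with attribute `degenerate = TRUE`.
#'
#' @param dend an `hclust` object from [ward_cluster()].
#' @param k_max largest k considered (default `n - 1`).
#' @return Integer k, with attribute `degenerate`.
#' @export
choose_k_elbow <- function(dend, k_max = NULL) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  if (n < 3) {
    k <- if (n == 1) 1L else 2L
    attr(k, "degenerate") <- FALSE
    return(k)
  }
  k_max <- min(k_max %||% (n - 1L), n - 1L)
  h <- dend$height                      # ascending, length n-1
  if (isTRUE(attr(dend, "degenerate_input")) ||
      max(h) - min(h) < 1e-12 * max(max(h), 1)) {
    k <- 1L
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  # gap(k) = h[n-k+1] - h[n-k]: jump incurred by merging below k clusters
  ks <- 2:k_max
  gaps <- h[n - ks + 1] - h[n - ks]
  k <- ks[which.max(gaps)]
  attr(k, "degenerate") <- FALSE
  k
}

#' Pick one representative trait per cluster
#'
#' For each cluster, the first eigenvector of the cluster's correlation
#' submatrix defines the cluster principal component; the representative is
#' the trait with the largest absolute coefficient on it (the trait most
#' correlated with the component). Singletons represent themselves; exact
#' ties go to the lowest trait index.
#'
#' @param rg correlation submatrix over the clustered traits.
#' @param partition integer cluster assignment (e.g. from
#'   `stats::cutree`), aligned with the rows of `rg`.
#' @return Named integer vector: representative trait index (into `rg`)
#'   per cluster, names = cluster labels.
#' @export
select_representatives <- function(rg, partition) {
  check_corr_matrix(rg)
  stopifnot(length(partition) == nrow(rg))
  reps <- integer(0)
  for (g in sort(unique(partition))) {
    idx <- which(partition == g)
    if (length(idx) == 1L) {
      reps[as.character(g)] <- idx
      next
    }
    sub <- rg[idx, idx, drop = FALSE]
    v <- eigen(sub, symmetric = TRUE)$vectors[, 1]
    best <- which(abs(abs(v) - max(abs(v))) < 1e-12)[1]  # tie -> lowest index
    reps[as.character(g)] <- idx[best]
  }
  reps
}

#' End-to-end trait reduction
#'
#' Runs the full reduction: find the traits with at least one
#' `|rg| > threshold` partner, Ward-cluster that subset on `1 - |rg|`,
#' choose k by the elbow rule, pick cluster representatives via the cluster
#' principal component, and return them together with the traits that were
#' never in the high-correlation subset.
#'
#' @param rg labelled square genetic-correlation matrix.
#' @param threshold high-correlation threshold (default 0.80).
#' @param k_max maximum cluster count for the elbow search.
#' @return List of class `cluster_solution`: `clustered` (traits in the
#'   high-correlation subset), `assignment` (named cluster ids), `k`,
#'   `degenerate`, `representatives` (trait labels), `retained`
#'   (never-clustered traits), `independent` (representatives + retained),
#'   `dendrogram`.
#' @export
cluster_traits <- function(rg, threshold = 0.80, k_max = NULL) {
  check_corr_matrix(rg)
  labs <- rownames(rg) %||% paste0("trait", seq_len(nrow(rg)))
  dimnames(rg) <- list(labs, labs)
  hi <- high_corr_subset(rg, threshold)
  retained <- setdiff(labs, hi)
  if (length(hi) < 2) {
    return(structure(list(clustered = hi, assignment = NULL,
                          k = length(hi), degenerate = FALSE,
                          representatives = hi, retained = retained,
                          independent = c(hi, retained),
                          dendrogram = NULL),
                     class = "cluster_solution"))
  }
  sub <- rg[hi, hi, drop = FALSE]
  dend <- ward_cluster(sub)
  k <- choose_k_elbow(dend, k_max)
  part <- stats::cutree(dend, k = as.integer(k))
  reps_idx <- select_representatives(sub, part)
  reps <- hi[reps_idx]
  structure(list(clustered = hi, assignment = part, k = as.integer(k),
                 degenerate = isTRUE(attr(k, "degenerate")),
                 representatives = reps, retained = retained,
                 independent = c(reps, retained), dendrogram = dend),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("trait clustering: %d clustered traits -> k = %d clusters%s\n",
              length(x$clustered), x$k,
              if (x$degenerate) " (degenerate structure)" else ""))
  cat("representatives:", paste(x$representatives, collapse = ", "), "\n")
  cat(sprintf("independent traits: %d (%d representatives + %d retained)\n",
              length(x$independent), length(x$representatives),
              length(x$retained)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Convenience wrapper for downstream genetic-correlation screens over the
#' reduced trait panel.
#'
#' @param p vector of p-values.
#' @return BH-adjusted p-values.
#' @export
fdr_correct <- function(p) stats::p.adjust(p, method = "BH")
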