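# Unsupervised grouping of embedded samples.
#
# K-means is implemented natively (Lloyd iterations with k-means++ seeding
# and multiple restarts) because the per-iteration objective trace is part
# of the contract: the within-cluster sum of squares must be non-increasing
# across iterations and is recorded and asserted on every run. Hierarchical
# clustering delegates to stats::hclust (Lance-Williams agglomeration on
# Euclidean distances) with labels cut from the merge tree.

new_cluster_result <- function(labels, K, method, objective = NA_real_,
                               merge_history = NULL, extra = list()) {
  stopifnot(all(sort(unique(labels)) == seq_len(K)))
  structure(c(list(labels = as.integer(labels), K = as.integer(K),
                   method = method, objective = objective,
                   merge_history = merge_history), extra),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$method, "K =", x$K, "\n")
  cat("  sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  if (!is.na(x$objective)) cat("  WCSS:", signif(x$objective, 6L), "\n")
  invisible(x)
}

wcss_of <- function(emb, labels, K) {
  s <- 0
  for (k in seq_len(K)) {
    pts <- emb[labels == k, , drop = FALSE]
    if (nrow(pts))
      s <- s + sum((pts - rep(colMeans(pts), each = nrow(pts)))^2)
  }
  s
}

#' K-means clustering of an embedding
#'
#' Lloyd's algorithm with k-means++ initialisation, run `n_restarts` times
#' from the given seed; the restart with the lowest within-cluster sum of
#' squares (WCSS) wins. Iterations stop at an assignment fixed point or
#' after `max_iter` rounds. Clusters emptied during an update are repaired
#' by reassigning the point farthest from its centre. The WCSS after every
#' update is recorded (`wcss_history`) and checked to be non-increasing.
#'
#' @param emb numeric embedding matrix (samples in rows), all finite.
#' @param K number of clusters, `2 <= K <= n`.
#' @param n_restarts independent k-means++ restarts.
#' @param seed integer seed; identical inputs and seed give identical labels.
#' @param max_iter Lloyd iteration cap per restart.
#' @return a `cluster_result` with fields `labels` (1..K), `objective`
#'   (WCSS), `centers` and `wcss_history` of the winning restart.
#' @export
cluster_kmeans <- function(emb, K, n_restarts = 10L, seed = 1L,
                           max_iter = 300L) {
  emb <- as.matrix(unclass(emb))
  if (!all(is.finite(emb))) stop2("embedding contains non-finite values")
  n <- nrow(emb)
  if (!is_count(K) || K < 2L) stop2("K must be an integer >= 2")
  if (K > n) stop2("K = ", K, " exceeds the number of samples (", n, ")")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- kmeans_once(emb, K, max_iter)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    new_cluster_result(best$labels, K, "kmeans", objective = best$wcss,
                       extra = list(centers = best$centers,
                                    wcss_history = best$history,
                                    n_restarts = as.integer(n_restarts)))
  })
}

# squared Euclidean distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

kmeans_pp_init <- function(emb, K) {
  n <- nrow(emb)
  centers <- matrix(0, K, ncol(emb))
  centers[1L, ] <- emb[sample.int(n, 1L), ]
  d2 <- cross_dist2(emb, centers[1L, , drop = FALSE])[, 1L]
  for (k in seq_len(K)[-1L]) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k, ] <- emb[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, cross_dist2(emb, centers[k, , drop = FALSE])[, 1L])
  }
  centers
}

kmeans_once <- function(emb, K, max_iter) {
  n <- nrow(emb)
  centers <- kmeans_pp_init(emb, K)
  labels <- integer(n)
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- cross_dist2(emb, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: seed the empty cluster with the point farthest
    # from its assigned centre
    repeat {
      empty <- setdiff(seq_len(K), unique(new_labels))
      if (!length(empty)) break
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- empty[1L]
      d2[far, ] <- Inf; d2[far, empty[1L]] <- 0
    }
    for (k in seq_len(K))
      centers[k, ] <- colMeans(emb[new_labels == k, , drop = FALSE])
    history <- c(history, wcss_of(emb, new_labels, K))
    if (length(history) > 1L &&
        history[length(history)] > history[length(history) - 1L] + 1e-8)
      stop2("internal error: WCSS increased across a Lloyd iteration")
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  list(labels = labels, centers = centers,
       wcss = history[length(history)], history = history)
}

#' Agglomerative hierarchical clustering of an embedding
#'
#' Euclidean-distance agglomeration via [stats::hclust()] (Lance-Williams
#' updates; `ward` maps to `ward.D2`, the squared-Euclidean Ward criterion).
#' Labels are obtained by cutting the merge tree at `K` clusters and are
#' renumbered 1..K in order of first appearance. The merge history (pairs
#' and heights) is returned; heights are non-decreasing for the monotone
#' linkages (ward, complete, average).
#'
#' @inheritParams cluster_kmeans
#' @param linkage one of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @return a `cluster_result` with `merge_history` and the underlying
#'   `hclust` object (`tree`).
#' @export
cluster_hierarchical <- function(emb, K,
                                 linkage = c("ward", "average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  emb <- as.matrix(unclass(emb))
  if (!all(is.finite(emb))) stop2("embedding contains non-finite values")
  n <- nrow(emb)
  if (!is_count(K) || K < 1L || K > n)
    stop2("K must be an integer in [1, n]")
  method <- c(ward = "ward.D2", average = "average", complete = "complete",
              single = "single")[[linkage]]
  tree <- stats::hclust(stats::dist(emb), method = method)
  raw <- stats::cutree(tree, k = K)
  labels <- match(raw, unique(raw))  # renumber in order of first appearance
  new_cluster_result(labels, K, "hierarchical",
                     merge_history = data.frame(a = tree$merge[, 1L],
                                                b = tree$merge[, 2L],
                                                height = tree$height),
                     extra = list(linkage = linkage, tree = tree))
}

#' Euclidean distance matrix between embedded samples
#'
#' @param emb numeric matrix, samples in rows.
#' @return symmetric `n x n` matrix with a zero diagonal.
#' @export
pairwise_distances <- function(emb) {
  emb <- as.matrix(unclass(emb))
  if (!all(is.finite(emb))) stop2("embedding contains non-finite values")
  as.matrix(stats::dist(emb))
}

#' Export cluster assignments as TSV
#'
#' Columns: sample ID, method, K, cluster label.
#' @param res a `cluster_result`.
#' @param ids sample identifiers.
#' @param path output path.
#' @export
write_clusters <- function(res, ids, path) {
  stopifnot(inherits(res, "cluster_result"))
  data.table::fwrite(data.frame(sample = ids, method = res$method,
                                K = res$K, cluster = res$labels),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
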