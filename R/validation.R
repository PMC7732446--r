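# Internal cluster-validity indexes and the optimal-K scan.
#
# Both indexes are computed in the same embedding space that was clustered.
# Silhouette: s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean
# within-cluster distance excluding self and b(i) the smallest mean
# distance to another cluster; members of singleton clusters score 0, as do
# points with a(i) = b(i) = 0. Davies-Bouldin:
# DBI = (1/K) sum_i max_{j != i} (S_i + S_j) / M_ij with S_i the mean
# member-to-centroid distance and M_ij the centroid separation.

check_labels <- function(emb, labels) {
  emb <- as.matrix(unclass(emb))
  if (!all(is.finite(emb))) stop2("embedding contains non-finite values")
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  labels <- as.integer(as.factor(labels))
  if (length(labels) != nrow(emb))
    stop2("labels length does not match the number of samples")
  list(emb = emb, labels = labels, K = max(labels))
}

#' Mean silhouette coefficient
#'
#' @param emb numeric embedding matrix (samples in rows).
#' @param labels cluster labels (vector or `cluster_result`); at least two
#'   distinct clusters.
#' @return mean silhouette over all samples, in `[-1, 1]`; higher means
#'   tighter, better-separated clusters.
#' @export
silhouette_score <- function(emb, labels) {
  x <- check_labels(emb, labels)
  n <- nrow(x$emb); K <- x$K
  if (K < 2L) stop2("silhouette needs at least two clusters")
  if (n < 3L) stop2("silhouette needs at least three samples")
  D <- pairwise_distances(x$emb)
  sizes <- tabulate(x$labels, K)
  ind <- matrix(0, n, K)
  ind[cbind(seq_len(n), x$labels)] <- 1
  S <- D %*% ind  # S[i, k] = total distance from i to members of cluster k
  own <- sizes[x$labels]
  a <- S[cbind(seq_len(n), x$labels)] / pmax(own - 1L, 1L)
  Smean <- S / rep(sizes, each = n)
  Smean[cbind(seq_len(n), x$labels)] <- Inf
  b <- apply(Smean, 1L, min)
  s <- ifelse(own == 1L, 0, (b - a) / pmax(pmax(a, b), .Machine$double.xmin))
  s[pmax(a, b) == 0 & own > 1L] <- 0  # identical points across clusters
  mean(s)
}

#' Davies-Bouldin index
#'
#' @inheritParams silhouette_score
#' @return nonnegative real; lower means more compact, better-separated
#'   clusters. Errors if two cluster centroids coincide (the index divides
#'   by their separation).
#' @export
davies_bouldin <- function(emb, labels) {
  x <- check_labels(emb, labels)
  K <- x$K
  if (K < 2L) stop2("Davies-Bouldin needs at least two clusters")
  centroids <- matrix(0, K, ncol(x$emb))
  S <- numeric(K)
  for (k in seq_len(K)) {
    pts <- x$emb[x$labels == k, , drop = FALSE]
    centroids[k, ] <- colMeans(pts)
    S[k] <- mean(sqrt(rowSums((pts - rep(centroids[k, ],
                                         each = nrow(pts)))^2)))
  }
  M <- pairwise_distances(centroids)
  off <- M[upper.tri(M)]
  if (any(off == 0))
    stop2("coincident cluster centroids: Davies-Bouldin is undefined ",
          "(zero centroid separation)")
  R <- outer(S, S, `+`) / M
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Scan candidate cluster counts and tabulate validity indexes
#'
#' Clusters the embedding at every K in `k_range` with the chosen method
#' and records the silhouette coefficient and Davies-Bouldin index per K —
#' the grid from which the optimal K is read. For hierarchical clustering
#' the tree is built once and cut at each K.
#'
#' @param emb numeric embedding matrix.
#' @param method `"kmeans"` or `"hierarchical"`.
#' @param k_range integer vector of candidate K (default 2:9).
#' @param seed seed for the K-means restarts (unused by hierarchical).
#' @param linkage,n_restarts passed through to the clustering functions.
#' @return a `validation_table`: data frame with columns `K`, `method`,
#'   `sc`, `dbi`.
#' @export
scan_k <- function(emb, method = c("kmeans", "hierarchical"),
                   k_range = 2:9, seed = 1L, linkage = "ward",
                   n_restarts = 10L) {
  method <- match.arg(method)
  emb <- as.matrix(unclass(emb))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop2("empty k_range")
  if (any(k_range < 2L)) stop2("k_range values must be >= 2")
  if (max(k_range) > nrow(emb))
    stop2("max(k_range) exceeds the number of samples")
  tree_fit <- NULL
  rows <- lapply(seq_along(k_range), function(i) {
    K <- k_range[i]
    labels <- if (method == "kmeans") {
      cluster_kmeans(emb, K, n_restarts = n_restarts, seed = seed + i)$labels
    } else {
      cluster_hierarchical(emb, K, linkage = linkage)$labels
    }
    data.frame(K = K, method = method,
               sc = silhouette_score(emb, labels),
               dbi = davies_bouldin(emb, labels))
  })
  structure(do.call(rbind, rows),
            class = c("validation_table", "data.frame"))
}

#' Select the optimal number of clusters from a validation table
#'
#' Picks the K with the maximal silhouette (`sc_max`, the default) or the
#' minimal Davies-Bouldin index (`dbi_min`). Ties (values equal within
#' `tol`) are broken toward the smaller K. When the two criteria point to
#' different K, a message flags the disagreement and an attribute
#' `disagreement` records both choices; the requested criterion still
#' decides.
#'
#' @param table a `validation_table` from [scan_k()].
#' @param criterion `"sc_max"` or `"dbi_min"`.
#' @param tol numeric tolerance within which index values count as tied.
#' @return the selected K (integer), with attribute `disagreement` if the
#'   criteria disagree.
#' @export
select_k <- function(table, criterion = c("sc_max", "dbi_min"), tol = 1e-12) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop2("empty validation table")
  pick <- function(values, maximize) {
    best <- if (maximize) max(values) else min(values)
    hit <- if (maximize) values >= best - tol else values <= best + tol
    min(table$K[hit])  # smallest-K tie-break
  }
  k_sc <- pick(table$sc, TRUE)
  k_dbi <- pick(table$dbi, FALSE)
  out <- if (criterion == "sc_max") k_sc else k_dbi
  if (k_sc != k_dbi) {
    message("select_k: criteria disagree (silhouette -> K = ", k_sc,
            ", Davies-Bouldin -> K = ", k_dbi, "); using ", criterion)
    attr(out, "disagreement") <- c(sc_max = k_sc, dbi_min = k_dbi)
  }
  out
}

#' @export
print.validation_table <- function(x, ...) {
  cat("validation_table (", paste(unique(x$method), collapse = ", "),
      "), K = ", min(x$K), "..", max(x$K), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4L)
  invisible(x)
}
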