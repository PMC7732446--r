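# Cross-tab evaluation of predicted clusters against known subpopulations.
#
# Clusters carry arbitrary numbers, so before counting correct assignments
# each cluster is matched to a subpopulation by the injective map that
# maximises the total matched count (optimal assignment, solved exactly by
# dynamic programming over column subsets; identical to majority matching
# for the 2x2 case). Unmatched clusters (when K > G) contribute zero
# correct assignments. The headline statistic is
#     %CA = 100 * matched count / n,
# reported both raw and rounded half-up to the nearest integer percent.

#' Contingency table of clusters vs. true subpopulations
#'
#' @param pred predicted cluster labels (vector or `cluster_result`).
#' @param truth known subpopulation labels, same length, with at least two
#'   distinct values.
#' @return a `confusion_table` holding the K x G count matrix (rows =
#'   clusters, columns = subpopulations); matching and accuracy are filled
#'   in by [match_clusters()] and [percent_correct()].
#' @export
cross_tab <- function(pred, truth) {
  if (inherits(pred, "cluster_result")) pred <- pred$labels
  if (length(pred) == 0L) stop2("empty input")
  if (length(pred) != length(truth))
    stop2("pred and truth lengths differ (", length(pred), " vs ",
          length(truth), ")")
  if (length(unique(truth)) < 2L)
    stop2("truth must contain at least two distinct subpopulations")
  counts <- unclass(table(cluster = pred, subpopulation = truth))
  structure(list(counts = counts, matching = NULL), class = "confusion_table")
}

#' Build a confusion table from precomputed counts
#'
#' Replay entry point: wraps an existing cluster-by-subpopulation count
#' matrix (e.g. a published cross-tab) so the matching and %CA arithmetic
#' can be verified independently of any clustering run.
#' @param counts nonnegative integer matrix, clusters in rows.
#' @export
confusion_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be nonnegative integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cluster", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("pop", seq_len(ncol(counts)))
  structure(list(counts = counts, matching = NULL), class = "confusion_table")
}

# Exact optimal assignment of rows (clusters) to distinct columns
# (subpopulations) by suffix DP over column bitmasks; ties prefer the
# identity-order mapping (row i -> column i where possible).
assign_rows <- function(counts) {
  K <- nrow(counts); G <- ncol(counts)
  if (max(K, G) > 12L)
    stop2("optimal assignment supports at most 12 clusters/subpopulations")
  # pad with zero columns so every row gets a (possibly dummy) column
  Gp <- max(K, G)
  C <- cbind(counts, matrix(0, K, Gp - G))
  nmask <- bitwShiftL(1L, Gp)
  bits <- bitwShiftL(1L, seq_len(Gp) - 1L)
  # val[r, mask+1] = best total over rows r..K with used-column set `mask`
  val <- matrix(0, K + 1L, nmask)
  for (r in K:1) {
    for (mask in 0:(nmask - 1L)) {
      bestv <- -Inf
      for (g in seq_len(Gp)) {
        if (bitwAnd(mask, bits[g]) == 0L) {
          v <- C[r, g] + val[r + 1L, bitwOr(mask, bits[g]) + 1L]
          if (v > bestv) bestv <- v
        }
      }
      val[r, mask + 1L] <- bestv
    }
  }
  total <- val[1L, 1L]
  # forward reconstruction; on ties try column r first, then ascending
  assign <- integer(K)
  mask <- 0L
  for (r in seq_len(K)) {
    for (g in unique(c(min(r, Gp), seq_len(Gp)))) {
      if (bitwAnd(mask, bits[g]) != 0L) next
      if (C[r, g] + val[r + 1L, bitwOr(mask, bits[g]) + 1L] ==
          val[r, mask + 1L]) {
        assign[r] <- g
        mask <- bitwOr(mask, bits[g])
        break
      }
    }
  }
  list(assign = assign, matched = total)
}

#' Match clusters to subpopulations
#'
#' Finds the injective cluster-to-subpopulation map that maximises the
#' total matched count. For the two-cluster, two-subpopulation case this is
#' simply the orientation with the larger trace; in general it is the
#' optimal assignment. Ties are broken toward the identity-order mapping.
#'
#' @param t a `confusion_table`.
#' @return `t` with `matching` filled: a named integer vector mapping each
#'   cluster (row) to a subpopulation column index, `NA` for unmatched
#'   clusters when K > G.
#' @export
match_clusters <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  res <- assign_rows(t$counts)
  matching <- res$assign
  matching[matching > ncol(t$counts)] <- NA_integer_  # dummy columns
  names(matching) <- rownames(t$counts)
  t$matching <- matching
  t$matched_count <- res$matched
  t
}

#' Percentage of correctly assigned individuals (%CA)
#'
#' `100 * matched count / n` under the optimal cluster-subpopulation
#' matching, rounded half-up to the nearest integer percent (the convention
#' used when quoting whole-percent assignment accuracies); the unrounded
#' value is attached as attribute `raw`.
#'
#' @param t a `confusion_table` (matching is computed if absent).
#' @return rounded percent in `[0, 100]` with attributes `raw` and
#'   `matched_count`.
#' @export
percent_correct <- function(t) {
  stopifnot(inherits(t, "confusion_table"))
  n <- sum(t$counts)
  if (n == 0L) stop2("empty confusion table")
  if (is.null(t$matching)) t <- match_clusters(t)
  raw <- 100 * t$matched_count / n
  structure(round_half_up(raw), raw = raw, matched_count = t$matched_count)
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("confusion_table (", nrow(x$counts), " clusters x ", ncol(x$counts),
      " subpopulations, n = ", sum(x$counts), ")\n", sep = "")
  print(x$counts)
  if (!is.null(x$matching)) {
    ok <- !is.na(x$matching)
    cat("  matching:",
        paste(names(x$matching)[ok], colnames(x$counts)[x$matching[ok]],
              sep = " -> ", collapse = ", "),
        if (any(!ok)) paste0(" (unmatched: ",
                             paste(names(x$matching)[!ok], collapse = ", "), ")")
        else "", "\n")
    pc <- percent_correct(x)
    cat(sprintf("  %%CA: %d%% (raw %.2f%%)\n", as.integer(pc), attr(pc, "raw")))
  }
  invisible(x)
}

#' Export a confusion report as TSV
#'
#' The count grid plus the matching and both raw and rounded %CA.
#' @param t a `confusion_table`.
#' @param path output path.
#' @export
write_confusion_tsv <- function(t, path) {
  stopifnot(inherits(t, "confusion_table"))
  if (is.null(t$matching)) t <- match_clusters(t)
  pc <- percent_correct(t)
  df <- data.frame(cluster = rownames(t$counts), t$counts,
                   matched_to = ifelse(is.na(t$matching), "",
                                       colnames(t$counts)[t$matching]),
                   check.names = FALSE)
  df$percent_correct <- c(as.numeric(pc), rep(NA, nrow(df) - 1L))
  df$percent_correct_raw <- c(attr(pc, "raw"), rep(NA, nrow(df) - 1L))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
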