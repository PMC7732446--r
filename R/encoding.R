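# Numeric encodings of nucleotide calls.
#
# Two schemes are supported and carried as a `scheme` attribute so that
# downstream stages can refuse mismatched inputs:
#   * one-hot: each call becomes a 4-vector in channel order (A, T, G, C),
#     i.e. A -> [1,0,0,0], T -> [0,1,0,0], G -> [0,0,1,0], C -> [0,0,0,1];
#     missing calls become the all-zero block. Columns are locus-major.
#   * label:   A -> 0, T -> 1, G -> 2, C -> 3; missing -> -1, a reserved
#     code that clustering and reduction stages reject.

new_encoded_matrix <- function(values, scheme, locus_ids) {
  structure(values,
            scheme = scheme,
            locus_ids = locus_ids,
            class = c("encoded_matrix", "matrix", "array"))
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("encoded_matrix (", attr(x, "scheme"), "): ", nrow(x), " samples x ",
      ncol(x), " columns (", length(attr(x, "locus_ids")), " loci)\n", sep = "")
  invisible(x)
}

encoding_scheme <- function(e) attr(e, "scheme")

#' One-hot encode a genotype matrix
#'
#' Expands each nucleotide call into a 4-channel indicator block in the
#' fixed channel order (A, T, G, C), giving an `n x 4L` numeric matrix with
#' locus-major column layout (`locus1_A, locus1_T, locus1_G, locus1_C,
#' locus2_A, ...`). Missing calls encode as all-zero blocks and contribute
#' no target mass to the autoencoder loss.
#'
#' @param m an [snp_matrix()].
#' @return an `encoded_matrix` with scheme `"one_hot"`.
#' @export
one_hot_encode <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  calls <- m$calls
  n <- nrow(calls); L <- ncol(calls)
  E <- matrix(0, nrow = n, ncol = 4L * L)
  for (c in seq_along(NUC_ORDER)) {
    hit <- which(calls == NUC_ORDER[c])
    if (length(hit)) {
      i <- (hit - 1L) %% n + 1L
      j <- (hit - 1L) %/% n + 1L
      E[cbind(i, (j - 1L) * 4L + c)] <- 1
    }
  }
  rownames(E) <- rownames(calls)
  colnames(E) <- paste(rep(colnames(calls), each = 4L), NUC_ORDER, sep = "_")
  new_encoded_matrix(E, "one_hot", colnames(calls))
}

#' Label-encode a genotype matrix
#'
#' Maps calls to integer codes A=0, T=1, G=2, C=3 (an `n x L` matrix).
#' Missing calls receive the reserved code -1; matrices containing -1 are
#' rejected by the reduction and clustering stages, so filter missing data
#' out first (see [filter_loci()]).
#'
#' @param m an [snp_matrix()].
#' @return an `encoded_matrix` with scheme `"label"`.
#' @export
label_encode <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  calls <- m$calls
  codes <- match(calls, NUC_ORDER) - 1L
  codes[is.na(codes)] <- -1L  # missing sentinel
  E <- matrix(as.numeric(codes), nrow = nrow(calls),
              dimnames = dimnames(calls))
  new_encoded_matrix(E, "label", colnames(calls))
}

#' Decode a one-hot (or reconstruction-probability) matrix
#'
#' Inverts [one_hot_encode()]: each consecutive 4-column block is mapped to
#' the nucleotide of its largest channel, with ties broken in channel order
#' (A, T, G, C). All-zero blocks decode to missing. Because the argmax is
#' taken, the input may equally be the per-locus softmax probabilities
#' produced by [ae_reconstruct()].
#'
#' @param e an `encoded_matrix` with scheme `"one_hot"` (width divisible
#'   by 4).
#' @return an [snp_matrix()].
#' @export
decode_one_hot <- function(e) {
  if (!is.matrix(e)) stop2("`e` must be a matrix")
  if (inherits(e, "encoded_matrix") && encoding_scheme(e) != "one_hot")
    stop2("decode_one_hot requires a one_hot encoded matrix, got scheme '",
          encoding_scheme(e), "'")
  d <- ncol(e)
  if (d %% 4L != 0L) stop2("matrix width ", d, " is not divisible by 4")
  L <- d %/% 4L
  channels <- lapply(1:4, function(c) e[, seq(c, d, by = 4L), drop = FALSE])
  # block argmax with first-wins tie-break in (A,T,G,C) order
  best <- channels[[1L]]
  pick <- matrix(1L, nrow(e), L)
  for (c in 2:4) {
    better <- channels[[c]] > best
    pick[better] <- c
    best[better] <- channels[[c]][better]
  }
  calls <- matrix(NUC_ORDER[pick], nrow = nrow(e))
  calls[best <= 0] <- MISSING_CALL  # all-zero block
  lids <- attr(e, "locus_ids") %||% sprintf("locus%0*d", nchar(L), seq_len(L))
  snp_matrix(calls, sample_ids = rownames(e), locus_ids = lids)
}

#' Export an encoded matrix as TSV
#'
#' Header row names channels (`locusID_A`, `locusID_T`, ...) for one-hot, or
#' locus IDs for label encoding; first column carries sample IDs.
#' @param e an `encoded_matrix` (or plain embedding matrix).
#' @param path output path.
#' @export
write_encoded_tsv <- function(e, path) {
  df <- data.frame(sample = rownames(e) %||% seq_len(nrow(e)),
                   as.data.frame(unclass(e)[, , drop = FALSE]),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
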