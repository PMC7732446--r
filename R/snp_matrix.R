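#' Construct an SNP genotype matrix
#'
#' The central genotype container: a sample-by-locus character matrix of
#' homozygous nucleotide calls (`"A"`, `"C"`, `"G"`, `"T"`) with `"N"` marking
#' missing data, plus optional known subpopulation labels used only for
#' evaluation. Inbred lines are assumed fully homozygous, so each call is a
#' single letter; heterozygous input is mapped to missing by the readers.
#'
#' @param calls character matrix (samples in rows, loci in columns) with
#'   entries in `A/C/G/T/N`. Row and column names, if absent, are taken from
#'   `sample_ids` / `locus_ids`.
#' @param sample_ids,locus_ids optional character vectors of unique
#'   identifiers; default to the dimnames of `calls`.
#' @param true_labels optional character vector of known subpopulation names,
#'   one per sample (used by [cross_tab()] and the pipeline's evaluation
#'   stage, never by the unsupervised stages).
#' @return An object of class `snp_matrix`.
#' @seealso [read_genotype_table()], [simulate_panel()]
#' @export
#' @examples
#' calls <- matrix(c("A", "A", "T", "T", "G", "G"), nrow = 3,
#'                 dimnames = list(paste0("s", 1:3), c("L1", "L2")))
#' snp_matrix(calls)
snp_matrix <- function(calls, sample_ids = NULL, locus_ids = NULL,
                       true_labels = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop2("`calls` must be a character matrix (samples x loci)")
  sample_ids <- sample_ids %||% rownames(calls)
  locus_ids <- locus_ids %||% colnames(calls)
  if (is.null(sample_ids))
    sample_ids <- sprintf("sample%0*d", nchar(nrow(calls)), seq_len(nrow(calls)))
  if (is.null(locus_ids))
    locus_ids <- sprintf("locus%0*d", nchar(ncol(calls)), seq_len(ncol(calls)))
  dimnames(calls) <- list(as.character(sample_ids), as.character(locus_ids))
  obj <- structure(list(calls = calls, true_labels = true_labels),
                   class = "snp_matrix")
  validate_snp_matrix(obj)
}

validate_snp_matrix <- function(m) {
  calls <- m$calls
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop2("empty genotype matrix: need at least one sample and one locus")
  if (anyDuplicated(rownames(calls)))
    stop2("duplicated sample IDs: ",
          paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop2("duplicated locus IDs: ",
          paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  bad <- !(calls %in% c(NUC_ORDER, MISSING_CALL))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop2("invalid genotype call '", calls[i], "' at sample '",
          rownames(calls)[(i - 1L) %% nrow(calls) + 1L],
          "' (calls must be A/C/G/T or N)")
  }
  if (!is.null(m$true_labels)) {
    if (length(m$true_labels) != nrow(calls))
      stop2("true_labels length (", length(m$true_labels),
            ") does not match sample count (", nrow(calls), ")")
    m$true_labels <- as.character(m$true_labels)
  }
  m
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix:", n_samples(x), "samples x", n_loci(x), "loci\n")
  nmiss <- sum(x$calls == MISSING_CALL)
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)", 100 * nmiss / length(x$calls)), "\n")
  if (!is.null(x$true_labels)) {
    tab <- table(x$true_labels)
    cat("  true labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$calls)

#' Sample and locus accessors
#' @param m an `snp_matrix`
#' @return character vector of identifiers, or an integer count.
#' @export
sample_ids <- function(m) rownames(m$calls)

#' @rdname sample_ids
#' @export
locus_ids <- function(m) colnames(m$calls)

#' @rdname sample_ids
#' @export
n_samples <- function(m) nrow(m$calls)

#' @rdname sample_ids
#' @export
n_loci <- function(m) ncol(m$calls)
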