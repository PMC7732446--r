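# Principal component analysis baseline for dimensionality reduction.
#
# Computed by singular value decomposition of the column-centred data
# (no scaling). The sign of each component is fixed so that its
# largest-magnitude loading is positive, which makes fits bit-reproducible.

#' Fit a PCA model
#'
#' @param data numeric matrix or `encoded_matrix` (one-hot input is the
#'   recommended default; label-encoded input is accepted with a warning
#'   because the integer codes impose an artificial ordering A < T < G < C).
#' @param n_components number of components to retain; at most
#'   `min(n - 1, d)`.
#' @return a `pca_model` with fields `column_means`, `components`
#'   (orthonormal rows, `n_components x d`), `explained_variance`
#'   (non-increasing) and `total_variance`.
#' @export
pca_fit <- function(data, n_components = 40L) {
  if (inherits(data, "encoded_matrix") && encoding_scheme(data) == "label") {
    if (any(data == -1))
      stop2("label-encoded input contains missing codes (-1); filter first")
    warning("fitting PCA on label-encoded genotypes imposes an artificial ",
            "ordinality A < T < G < C; one-hot input is recommended",
            call. = FALSE)
  }
  X <- as.matrix(unclass(data))
  n <- nrow(X); d <- ncol(X)
  maxc <- min(n - 1L, d)
  if (!is_count(n_components) || n_components > maxc)
    stop2("n_components must be a positive integer <= min(n - 1, d) = ", maxc)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = n)
  total_var <- sum(Xc^2) / (n - 1L)
  if (total_var <= 0) stop2("zero-variance data: PCA is undefined")
  sv <- svd(Xc, nu = 0L, nv = n_components)
  comp <- t(sv$v)
  # sign convention: largest-magnitude loading of each component positive
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(column_means = mu,
                 components = comp,
                 explained_variance = (sv$d[seq_len(n_components)]^2) / (n - 1L),
                 total_variance = total_var),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", nrow(x$components), "components x",
      ncol(x$components), "variables\n")
  pct <- 100 * x$explained_variance / x$total_variance
  cat("  variance explained:",
      paste0(signif(utils::head(pct, 5L), 3L), "%", collapse = ", "),
      if (length(pct) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Project data onto fitted principal components
#'
#' Centres `data` with the training column means and projects it onto the
#' component rows, yielding an `n x m` embedding (scores).
#'
#' @param model a `pca_model`.
#' @param data matrix with the same width the model was fitted on.
#' @return numeric score matrix, samples in rows.
#' @export
pca_transform <- function(model, data) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(unclass(data))
  if (ncol(X) != length(model$column_means))
    stop2("data width ", ncol(X), " does not match the fitted width ",
          length(model$column_means))
  S <- (X - rep(model$column_means, each = nrow(X))) %*% t(model$components)
  rownames(S) <- rownames(X)
  colnames(S) <- paste0("pc", seq_len(ncol(S)))
  S
}
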