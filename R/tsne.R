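# Exact t-distributed stochastic neighbor embedding (t-SNE) for 2-D
# visualisation of embeddings.
#
# This is the classical exact O(n^2) algorithm: per-point Gaussian
# bandwidths found by bisection to hit the target perplexity, symmetrised
# input affinities, Student-t (1 df) output affinities, gradient descent
# with momentum (0.5 for the first 250 iterations, 0.8 after) and early
# exaggeration (factor 4 for the first 100 iterations). Panels in this
# package are small (hundreds of lines), so the quadratic cost is
# immaterial and no tree approximation is needed. Runs are deterministic
# given the seed.

# conditional Gaussian affinities at the bandwidth matching log-perplexity
tsne_input_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

#' Two-dimensional t-SNE embedding
#'
#' Maps an embedding (typically the autoencoder bottleneck) to 2-D for
#' visual inspection of subpopulation structure. Defaults follow common
#' practice for SNP-panel visualisation: perplexity 30, 1,000 iterations,
#' learning rate 200. Feasibility requires `perplexity < (n - 1) / 3`.
#'
#' @param emb numeric matrix, samples in rows (`n >= 10`).
#' @param perplexity effective neighbourhood size.
#' @param iterations gradient-descent iterations.
#' @param learning_rate gradient step size.
#' @param seed integer seed for the random initialisation.
#' @param labels optional per-sample labels carried into the result.
#' @return a `plot_frame`: data frame with columns `sample`, `dim1`,
#'   `dim2`, `label`, with axis names in attribute `axes`.
#' @export
tsne_embed <- function(emb, perplexity = 30, iterations = 1000L,
                       learning_rate = 200, seed = 1L, labels = NULL) {
  emb <- as.matrix(unclass(emb))
  n <- nrow(emb)
  if (n < 10L) stop2("t-SNE needs at least 10 samples")
  if (perplexity >= (n - 1) / 3)
    stop2("perplexity ", perplexity, " is infeasible for n = ", n,
          " (requires perplexity < (n - 1)/3 = ", signif((n - 1) / 3, 4), ")")
  if (!all(is.finite(emb))) stop2("embedding contains non-finite values")
  D2 <- cross_dist2(emb, emb)
  P <- tsne_input_affinities(D2, perplexity)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
    G <- matrix(0, n, 2L)   # momentum accumulator
    gains <- matrix(1, n, 2L)
    for (it in seq_len(iterations)) {
      ex <- if (it <= 100L) 4 else 1
      momentum <- if (it <= 250L) 0.5 else 0.8
      # Student-t output affinities
      num <- 1 / (1 + cross_dist2(Y, Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), .Machine$double.xmin)
      W <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      # adaptive gains as in the reference implementation
      same <- sign(grad) == sign(G)
      gains <- pmax(ifelse(same, gains * 0.8, gains + 0.2), 0.01)
      G <- momentum * G - learning_rate * gains * grad
      Y <- Y + G
      Y <- Y - rep(colMeans(Y), each = n)
    }
    plot_frame(Y, labels = labels, ids = rownames(emb),
               axes = c("t-SNE 1", "t-SNE 2"))
  })
}

#' Assemble a 2-D plot frame
#'
#' @param coords n x 2 numeric matrix of coordinates.
#' @param labels optional per-sample labels (subpopulation or cluster).
#' @param ids optional sample identifiers.
#' @param axes length-2 character vector of axis names.
#' @return a `plot_frame` data frame.
#' @export
plot_frame <- function(coords, labels = NULL, ids = NULL,
                       axes = c("dim1", "dim2")) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop2("coordinates must have exactly two columns")
  if (!all(is.finite(coords))) stop2("coordinates must be finite")
  n <- nrow(coords)
  if (!is.null(labels) && length(labels) != n)
    stop2("labels length does not match the number of points")
  df <- data.frame(sample = ids %||% rownames(coords) %||% as.character(seq_len(n)),
                   dim1 = coords[, 1L], dim2 = coords[, 2L],
                   label = if (is.null(labels)) NA_character_ else as.character(labels),
                   stringsAsFactors = FALSE)
  structure(df, axes = axes, class = c("plot_frame", "data.frame"))
}
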