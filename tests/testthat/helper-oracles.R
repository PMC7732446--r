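# Independent brute-force oracles and small fixture builders. These are
# deliberately written in the most literal way possible (double loops,
# exhaustive enumeration) so they share no code path with the package
# implementations they check.

rand_snp_matrix <- function(n, L, seed, missing = 0) {
  set.seed(seed)
  calls <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                  nrow = n)
  if (missing > 0) calls[runif(n * L) < missing] <- "N"
  snp_matrix(calls,
             sample_ids = paste0("s", seq_len(n)),
             locus_ids = paste0("L", seq_len(L)))
}

# literal per-locus minor allele frequency: tally, take second-largest
maf_bf <- function(column) {
  x <- column[column != "N"]
  if (length(x) == 0) return(NA_real_)
  counts <- sort(table(x), decreasing = TRUE)
  if (length(counts) < 2) return(0)
  as.numeric(counts[2]) / length(x)
}

# silhouette by the textbook a/b/s formulas, all double loops
silhouette_bf <- function(emb, labels) {
  n <- nrow(emb)
  d <- function(i, j) sqrt(sum((emb[i, ] - emb[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), 0)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Davies-Bouldin by the definition: scatters, centroid separations, worst
# ratio per cluster
dbi_bf <- function(emb, labels) {
  cls <- sort(unique(labels))
  K <- length(cls)
  cent <- lapply(cls, function(k) colMeans(emb[labels == k, , drop = FALSE]))
  S <- vapply(seq_len(K), function(k) {
    mem <- which(labels == cls[k])
    mean(vapply(mem, function(i) sqrt(sum((emb[i, ] - cent[[k]])^2)), 0))
  }, 0)
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / K
}

wcss_bf <- function(emb, labels) {
  s <- 0
  for (k in unique(labels)) {
    pts <- emb[labels == k, , drop = FALSE]
    ctr <- colMeans(pts)
    for (i in seq_len(nrow(pts))) s <- s + sum((pts[i, ] - ctr)^2)
  }
  s
}

# global two-cluster WCSS optimum by exhaustive enumeration of all
# 2-partitions (feasible for n <= 12)
best_wcss_k2_bf <- function(emb) {
  n <- nrow(emb)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 1
    labels <- c(1L, as.integer(intToBits(code)[seq_len(n - 1)]) + 1L)
    if (length(unique(labels)) < 2) next
    best <- min(best, wcss_bf(emb, labels))
  }
  best
}

# all permutations of 1..n (for assignment brute force)
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# best matched count over all injective row->column maps, brute force
best_match_bf <- function(counts) {
  K <- nrow(counts); G <- ncol(counts)
  Gp <- max(K, G)
  C <- cbind(counts, matrix(0, K, Gp - G))
  best <- -Inf
  for (p in perms(Gp))
    best <- max(best, sum(C[cbind(seq_len(K), p[seq_len(K)])]))
  best
}

# two well-separated Gaussian blobs in `d` dimensions
two_blob_embedding <- function(n_per = 20, d = 3, gap = 10, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * d), ncol = d),
        matrix(rnorm(n_per * d) + gap, ncol = d))
}
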