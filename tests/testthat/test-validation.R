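test_that("silhouette boundary cases follow the standard conventions", {
  # two clusters of duplicated points: a = 0, b > 0 -> SC = 1
  emb <- rbind(matrix(1, 3, 2), matrix(9, 3, 2))
  expect_equal(silhouette_score(emb, rep(1:2, each = 3)), 1)
  # all-singleton clustering -> SC = 0
  emb2 <- matrix(rnorm(8), ncol = 2)
  expect_equal(silhouette_score(emb2, 1:4), 0)
  # identical points across clusters: a = b = 0 -> s defined as 0
  same <- matrix(1, 4, 2)
  expect_equal(silhouette_score(same, c(1, 1, 2, 2)), 0)
  expect_error(silhouette_score(emb2, rep(1, 4)), "two clusters")
})

test_that("silhouette matches the brute-force a/b/s formulas", {
  set.seed(21)
  emb <- matrix(rnorm(10), ncol = 2)  # 5 planted points
  labels <- c(1, 1, 2, 2, 2)
  expect_equal(silhouette_score(emb, labels), silhouette_bf(emb, labels),
               tolerance = 1e-12)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    emb <- matrix(rnorm(n * 2), ncol = 2)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_score(emb, labels), silhouette_bf(emb, labels),
                 tolerance = 1e-12)
  }
})

test_that("Davies-Bouldin matches hand arithmetic and the brute force", {
  # duplicated clusters: zero scatter -> DBI = 0
  emb <- rbind(matrix(0, 3, 1), matrix(5, 3, 1))
  expect_equal(davies_bouldin(emb, rep(1:2, each = 3)), 0)
  # {0,2} and {10,12}: S = 1 each, M = 10 -> DBI = 0.2
  emb2 <- matrix(c(0, 2, 10, 12), ncol = 1)
  expect_equal(davies_bouldin(emb2, c(1, 1, 2, 2)), 0.2, tolerance = 1e-12)
  set.seed(22)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    emb <- matrix(rnorm(n * 3), ncol = 3)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(davies_bouldin(emb, labels), dbi_bf(emb, labels),
                 tolerance = 1e-12)
  }
  # coincident centroids are an error (division by zero separation)
  sym <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  expect_error(davies_bouldin(sym, c(1, 1, 2, 2)), "coincident")
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  set.seed(23)
  emb <- matrix(rnorm(30), ncol = 2)
  labels <- sample(1:3, 15, replace = TRUE)
  skip_if(length(unique(labels)) < 2)
  ref <- mean(cluster::silhouette(labels, dist(emb))[, "sil_width"])
  expect_equal(silhouette_score(emb, labels), ref, tolerance = 1e-10)
})

test_that("index bounds hold over random labelings", {
  set.seed(24)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    emb <- matrix(rnorm(n * 2), ncol = 2)
    K <- sample(2:4, 1)
    labels <- c(seq_len(K), sample(seq_len(K), n - K, replace = TRUE))
    sc <- silhouette_score(emb, labels)
    expect_gte(sc, -1); expect_lte(sc, 1)
    expect_gte(davies_bouldin(emb, labels), 0)
  }
})

test_that("both indexes are invariant to rigid motion and uniform scaling", {
  set.seed(25)
  emb <- matrix(rnorm(24), ncol = 2)
  labels <- rep(1:3, each = 4)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  emb2 <- 3.7 * (emb %*% R) + 11
  expect_equal(silhouette_score(emb, labels), silhouette_score(emb2, labels),
               tolerance = 1e-10)
  expect_equal(davies_bouldin(emb, labels), davies_bouldin(emb2, labels),
               tolerance = 1e-10)
})

test_that("the K scan peaks at the planted cluster count", {
  emb <- two_blob_embedding(n_per = 15, gap = 12, seed = 26)
  for (method in c("kmeans", "hierarchical")) {
    vt <- scan_k(emb, method, k_range = 2:6, seed = 1)
    expect_equal(nrow(vt), 5)
    expect_equal(vt$K[which.max(vt$sc)], 2, label = method)
    expect_true(all(vt$sc[vt$K > 2] < max(vt$sc)))
    expect_equal(select_k(vt), 2)
  }
  one <- scan_k(emb, "hierarchical", k_range = 2)
  expect_equal(nrow(one), 1)
  a <- scan_k(emb, "kmeans", k_range = 2:4, seed = 9)
  b <- scan_k(emb, "kmeans", k_range = 2:4, seed = 9)
  expect_identical(a, b)
})

test_that("select_k breaks ties toward smaller K and flags disagreement", {
  tab <- structure(data.frame(K = c(2, 4, 5), method = "hierarchical",
                              sc = c(0.08, 0.08, 0.08),
                              dbi = c(2.9, 2.5, 2.7)),
                   class = c("validation_table", "data.frame"))
  expect_equal(suppressMessages(select_k(tab)), 2,
               ignore_attr = TRUE)  # equal SC at 2, 4, 5
  expect_equal(suppressMessages(select_k(tab, "dbi_min")), 4,
               ignore_attr = TRUE)
  expect_message(k <- select_k(tab), "disagree")
  expect_equal(attr(k, "disagreement"), c(sc_max = 2, dbi_min = 4))
  expect_error(select_k(tab[0, ]), "empty")
})

test_that("scan range is validated", {
  emb <- matrix(rnorm(12), ncol = 2)
  expect_error(scan_k(emb, "kmeans", k_range = integer(0)), "empty")
  expect_error(scan_k(emb, "kmeans", k_range = 1:3), ">= 2")
  expect_error(scan_k(emb, "kmeans", k_range = 2:10), "exceeds")
})
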