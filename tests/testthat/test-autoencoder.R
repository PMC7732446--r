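# Tiny architectures are used throughout; the full-width default is
# exercised by the end-to-end acceptance tests.

tiny_spec <- function(input_dim = 16, widths = 8, bottleneck = 3, lr = 0.01)
  ae_spec(input_dim, encoder_widths = widths, bottleneck_dim = bottleneck,
          learning_rate = lr)

test_that("layer shapes chain symmetrically through the bottleneck", {
  spec <- ae_spec(19248)  # 4,812 loci x 4 channels, default widths
  dims <- snpcluster:::ae_layer_dims(spec)
  expect_equal(dims, c(19248, 2000, 700, 40, 700, 2000, 19248))
  mod <- build_autoencoder(tiny_spec(), seed = 1)
  d <- snpcluster:::ae_layer_dims(mod$spec)
  for (l in seq_along(mod$W)) {
    expect_equal(dim(mod$W[[l]]), c(d[l], d[l + 1]))
    expect_length(mod$b[[l]], d[l + 1])
  }
})

test_that("invalid width chains are rejected", {
  expect_error(ae_spec(100, encoder_widths = 30, bottleneck_dim = 40),
               "narrow")
  expect_error(ae_spec(100, encoder_widths = 120, bottleneck_dim = 10),
               "narrow")
  expect_error(ae_spec(10))  # not wide enough for the default widths
})

test_that("weight initialisation is reproducible from the seed", {
  a <- build_autoencoder(tiny_spec(), seed = 42)
  b <- build_autoencoder(tiny_spec(), seed = 42)
  c <- build_autoencoder(tiny_spec(), seed = 43)
  expect_identical(a$W, b$W)
  expect_false(identical(a$W, c$W))
  # He-uniform bound for the first layer: sqrt(6 / fan_in)
  expect_lte(max(abs(a$W[[1]])), sqrt(6 / 16))
})

test_that("training reduces the loss and is deterministic given the seed", {
  m <- rand_snp_matrix(20, 4, seed = 5)
  e <- one_hot_encode(m)
  mod <- build_autoencoder(tiny_spec(), seed = 1)
  fit1 <- ae_train(mod, e, epochs = 60, batch_size = 8, seed = 2)
  expect_length(fit1$loss_history, 60)
  expect_true(all(is.finite(fit1$loss_history)))
  expect_lt(tail(fit1$loss_history, 1), fit1$loss_history[1])
  fit2 <- ae_train(mod, e, epochs = 60, batch_size = 8, seed = 2)
  expect_identical(fit1$loss_history, fit2$loss_history)
  # the input model must not be mutated by training (in-place updates are
  # confined to the trainee's copies)
  expect_identical(mod$W, build_autoencoder(tiny_spec(), seed = 1)$W)
  expect_false(mod$trained)
})

test_that("a tiny panel is memorised: argmax reconstruction equals the input", {
  m <- snp_matrix(matrix(c("A", "T", "G", "C",
                           "C", "G", "T", "A"), nrow = 4),
                  sample_ids = paste0("s", 1:4), locus_ids = c("L1", "L2"))
  e <- one_hot_encode(m)
  spec <- ae_spec(8, encoder_widths = 6, bottleneck_dim = 4,
                  learning_rate = 0.02)
  fit <- ae_train(build_autoencoder(spec, seed = 1), e,
                  epochs = 500, batch_size = 4, seed = 2)
  rec <- ae_reconstruct(fit, e)
  expect_identical(decode_one_hot(rec)$calls, m$calls)
  # reconstruction cross-entropy equals the loss formula evaluated externally
  ext <- -sum(unclass(e) * log(unclass(rec))) / sum(e)
  expect_equal(ae_loss(fit, e), ext, tolerance = 1e-12)
})

test_that("softmax reconstruction blocks are probability vectors", {
  m <- rand_snp_matrix(6, 5, seed = 11)
  e <- one_hot_encode(m)
  fit <- ae_train(build_autoencoder(tiny_spec(20, 10, 3), seed = 1), e,
                  epochs = 5, batch_size = 6, seed = 1)
  rec <- ae_reconstruct(fit, e)
  for (j in seq_len(5))
    expect_equal(unname(rowSums(rec[, (j - 1) * 4 + 1:4])), rep(1, 6),
                 tolerance = 1e-9)
})

test_that("encoding honours the shape contract and determinism", {
  m <- rand_snp_matrix(8, 4, seed = 6)
  # duplicate a row: identical inputs must embed identically
  calls <- m$calls; calls[2, ] <- calls[1, ]
  m <- snp_matrix(calls)
  e <- one_hot_encode(m)
  fit <- ae_train(build_autoencoder(tiny_spec(), seed = 2), e,
                  epochs = 10, batch_size = 4, seed = 3)
  emb <- ae_encode(fit, e)
  expect_equal(dim(emb), c(8, 3))
  expect_equal(emb[1, ], emb[2, ], ignore_attr = TRUE)
  expect_true(all(is.finite(emb)))
  # all-zero input row stays finite (bias path)
  zero <- snpcluster:::new_encoded_matrix(matrix(0, 1, 16), "one_hot", NULL)
  expect_true(all(is.finite(ae_encode(fit, zero))))
  expect_warning(ae_encode(build_autoencoder(tiny_spec(), seed = 2), e),
                 "untrained")
})

test_that("width mismatches and wrong schemes are refused", {
  m <- rand_snp_matrix(4, 4, seed = 7)
  mod <- build_autoencoder(tiny_spec(), seed = 1)
  expect_error(ae_train(mod, label_encode(m), epochs = 1, seed = 1),
               "one_hot")
  big <- one_hot_encode(rand_snp_matrix(4, 5, seed = 7))
  expect_error(ae_train(mod, big, epochs = 1, seed = 1), "width")
})

test_that("analytic gradients match central finite differences", {
  set.seed(8)
  m <- rand_snp_matrix(3, 2, seed = 8)
  e <- one_hot_encode(m)
  X <- unclass(e); attributes(X) <- attributes(X)[c("dim", "dimnames")]
  mod <- build_autoencoder(ae_spec(8, encoder_widths = 6, bottleneck_dim = 3),
                           seed = 9)
  g <- snpcluster:::ae_gradients(mod, X)
  h <- 1e-5
  check <- function(l, idx, analytic, field) {
    up <- mod; up[[field]][[l]][idx] <- up[[field]][[l]][idx] + h
    dn <- mod; dn[[field]][[l]][idx] <- dn[[field]][[l]][idx] - h
    num <- (snpcluster:::ae_gradients(up, X)$loss -
            snpcluster:::ae_gradients(dn, X)$loss) / (2 * h)
    expect_lt(abs(num - analytic) / max(abs(num), abs(analytic), 1e-8), 1e-5)
  }
  for (l in seq_along(mod$W)) {
    for (idx in sample(length(mod$W[[l]]), 5))
      check(l, idx, g$gW[[l]][idx], "W")
    for (idx in sample(length(mod$b[[l]]), 2))
      check(l, idx, g$gb[[l]][idx], "b")
  }
})

test_that("missing blocks contribute no loss mass", {
  calls <- matrix(c("A", "T", "N", "G"), nrow = 2)
  m <- snp_matrix(calls)
  e <- one_hot_encode(m)
  mod <- build_autoencoder(ae_spec(8, encoder_widths = 5, bottleneck_dim = 2),
                           seed = 1)
  X <- unclass(e); attributes(X) <- attributes(X)[c("dim", "dimnames")]
  g <- snpcluster:::ae_gradients(mod, X)
  Y <- snpcluster:::ae_forward(mod, X)$Y
  # literal masked cross-entropy: 3 observed calls out of 4
  manual <- -(sum(X * log(Y))) / 3
  expect_equal(g$loss, manual, tolerance = 1e-12)
})

test_that("depth search reports one sorted row per candidate", {
  m <- rand_snp_matrix(12, 6, seed = 10)
  e <- one_hot_encode(m)
  rep1 <- depth_search(e, depths = 1:3, seed = 5, epochs = 8,
                       batch_size = 6, bottleneck_dim = 2)
  expect_equal(nrow(rep1), 3)
  expect_setequal(rep1$depth, 1:3)
  expect_false(is.unsorted(rep1$final_loss))
  rep2 <- depth_search(e, depths = 1:3, seed = 5, epochs = 8,
                       batch_size = 6, bottleneck_dim = 2)
  expect_identical(rep1, rep2)
  single <- depth_search(e, depths = 2, seed = 5, epochs = 2,
                         batch_size = 6, bottleneck_dim = 2)
  expect_equal(nrow(single), 1)
  expect_error(depth_search(e, depths = integer(0)), "empty")
})

test_that("checkpoints round-trip the model", {
  m <- rand_snp_matrix(5, 4, seed = 12)
  e <- one_hot_encode(m)
  fit <- ae_train(build_autoencoder(tiny_spec(), seed = 1), e,
                  epochs = 3, batch_size = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  ae_save(fit, f)
  back <- ae_load(f)
  expect_identical(back$W, fit$W)
  expect_identical(ae_encode(back, e), ae_encode(fit, e))
})
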