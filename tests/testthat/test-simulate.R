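test_that("the default configuration emulates the reference panel shape", {
  m <- simulate_panel(sim_config(seed = 1))
  expect_equal(dim(m), c(183L, 4812L))
  expect_equal(table(m$true_labels), table(rep(c("pop1", "pop2"), c(97, 86))),
               ignore_attr = TRUE)
  # fully homozygous single-letter calls, no missing by default
  expect_true(all(m$calls %in% c("A", "C", "G", "T")))
})

test_that("simulation is reproducible from the seed", {
  cfg <- sim_config(lines_per_subpop = c(10, 10), n_loci = 50, seed = 11)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$calls, b$calls)
  c <- simulate_panel(sim_config(lines_per_subpop = c(10, 10), n_loci = 50,
                                 seed = 12))
  expect_false(identical(a$calls, c$calls))
})

test_that("each locus is biallelic with letters spanning the alphabet", {
  m <- simulate_panel(sim_config(lines_per_subpop = c(30, 30), n_loci = 200,
                                 seed = 2))
  n_alleles <- apply(m$calls, 2, function(x) length(unique(x)))
  expect_true(all(n_alleles <= 2))
  expect_setequal(unique(as.vector(m$calls)), c("A", "C", "G", "T"))
})

test_that("at F = 0 the subpopulations share allele frequencies", {
  cfg <- sim_config(lines_per_subpop = c(60, 60), n_loci = 2000, fst = 0,
                    seed = 3)
  m <- simulate_panel(cfg)
  # true frequencies coincide, so the observed difference is pure binomial
  # sampling noise: E|dp| = sqrt(2/pi) * sqrt(2 p(1-p)/60) ~ 0.066 here
  ref <- apply(m$calls, 2, function(x) sort(unique(x))[1])
  p1 <- colMeans(m$calls[1:60, ] == rep(ref, each = 60))
  p2 <- colMeans(m$calls[61:120, ] == rep(ref, each = 60))
  expect_lt(mean(abs(p1 - p2)), 0.08)
  # the corrected FST estimator removes that sampling floor
  expect_lt(abs(empirical_fst(m)), 0.02)
})

test_that("empirical FST is ~1 for fixed alternate alleles", {
  calls <- rbind(matrix("A", 10, 30), matrix("T", 10, 30))
  m <- snp_matrix(calls, true_labels = rep(c("p1", "p2"), each = 10))
  expect_gt(empirical_fst(m), 0.99)
})

test_that("empirical FST recovers the configured differentiation", {
  cfg <- sim_config(lines_per_subpop = c(60, 60), n_loci = 2000, fst = 0.3,
                    seed = 4)
  est <- empirical_fst(simulate_panel(cfg))
  expect_lt(abs(est - 0.3), 0.05)
})

test_that("the ancestral MAF spectrum respects the configured range", {
  cfg <- sim_config(lines_per_subpop = c(100, 100), n_loci = 5000, fst = 0,
                    ancestral_maf_range = c(0.15, 0.5), seed = 5)
  m <- simulate_panel(cfg)
  maf <- compute_locus_stats(m)$maf
  # sample MAF = binomial draw around the ancestral value; the bulk of the
  # spectrum must sit in the configured band and fill it
  expect_gt(mean(maf > 0.12 & maf <= 0.5), 0.97)
  expect_lt(abs(mean(maf) - 0.325), 0.02)
  expect_gt(max(maf), 0.45)
  expect_lt(min(maf), 0.2)
})

test_that("missingness is injected at the configured rate", {
  cfg <- sim_config(lines_per_subpop = c(40, 40), n_loci = 500,
                    missing_rate = 0.1, seed = 6)
  m <- simulate_panel(cfg)
  expect_lt(abs(mean(m$calls == "N") - 0.1), 0.01)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_subpops = 0), "at least one")
  expect_error(sim_config(lines_per_subpop = c(5, 5, 5)), "one entry per")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.5)), "range")
  expect_error(sim_config(n_loci = 0), "locus")
})

test_that("assignment accuracy rises with differentiation (end to end)", {
  # scaled-down panels so three autoencoder fits stay cheap
  acc <- vapply(c(0, 0.3, 0.5), function(f) {
    accs <- vapply(1:3, function(s) {
      cfg <- sim_config(lines_per_subpop = c(20, 20), n_loci = 300, fst = f,
                        seed = 100 + s)
      m <- simulate_panel(cfg)
      e <- one_hot_encode(m)
      spec <- ae_spec(ncol(e),
                      encoder_widths = snpcluster:::width_schedule(ncol(e), 10, 2),
                      bottleneck_dim = 10)
      fit <- ae_train(build_autoencoder(spec, seed = s), e, epochs = 30,
                      batch_size = 20, seed = s + 50)
      emb <- ae_encode(fit, e)
      ct <- match_clusters(cross_tab(cluster_hierarchical(emb, 2),
                                     m$true_labels))
      attr(percent_correct(ct), "raw")
    }, 0)
    mean(accs)
  }, 0)
  expect_true(all(diff(acc) >= -1e-9))
  expect_gt(acc[3], acc[1])
})
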