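test_that("matrix-format files parse into validated snp_matrix objects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tL1\tL2",
               "s1\tA\tT",
               "s2\tA\tA",
               "s3\tT\tT"), f)
  m <- read_genotype_table(f, "matrix")
  expect_s3_class(m, "snp_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sample_ids(m), c("s1", "s2", "s3"))
  expect_equal(locus_ids(m), c("L1", "L2"))
  expect_equal(unname(m$calls[1, ]), c("A", "T"))
})

test_that("duplicated sample IDs and empty files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tL1", "s1\tA", "s1\tT"), f)
  expect_error(read_genotype_table(f, "matrix"), "duplicated sample")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tL1", f2)
  expect_error(read_genotype_table(f2, "matrix"), "empty")
  expect_error(read_genotype_table("/nonexistent/file.tsv", "matrix"),
               "not found")
})

test_that("heterozygous and ambiguity calls map to missing (inbred convention)", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tL1\tL2\tL3",
               "s1\tR\tAT\t-",
               "s2\tA\tGG\t."), f)
  m <- read_genotype_table(f, "matrix")
  expect_equal(unname(m$calls[1, ]), c("N", "N", "N"))
  expect_equal(unname(m$calls[2, ]), c("A", "G", "N"))
  expect_error(read_genotype_table(f, "matrix", strict = TRUE), "strict")
})

test_that("VCF input: biallelic GT records parse; 0/1 becomes missing", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
               "1\t100\tsnp1\tA\tT\t.\tPASS\t.\tGT\t0/0\t1|1\t0/1",
               "1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t./.\t0/0"), f)
  m <- read_genotype_table(f, "vcf")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m$calls[, 1]), c("A", "T", "N"))  # het -> missing
  expect_equal(unname(m$calls[, 2]), c("C", "N", "G"))
  expect_equal(locus_ids(m), c("snp1", "1_200"))
})

test_that("non-biallelic or non-SNP VCF records are refused", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "1\t100\tx\tA\tT,C\t.\tPASS\t.\tGT\t0/0"), f)
  expect_error(read_genotype_table(f, "vcf"), "biallelic")
})

test_that("locus statistics match a brute-force allele tally", {
  m <- snp_matrix(matrix(c("A", "A", "A", "T",
                           "A", "A", "A", "A",
                           "A", "A", "T", "N"), nrow = 4,
                         dimnames = list(paste0("s", 1:4), paste0("L", 1:3))))
  st <- compute_locus_stats(m)
  expect_equal(st$maf, c(0.25, 0, 1 / 3))
  expect_equal(st$missing_fraction, c(0, 0, 0.25))
  # property: agreement with the literal tally on random matrices
  for (seed in 1:5) {
    r <- rand_snp_matrix(5, 5, seed = seed, missing = 0.2)
    st <- compute_locus_stats(r)
    expect_equal(st$maf, unname(apply(r$calls, 2, maf_bf)), tolerance = 1e-12)
  }
})

test_that("all-missing loci are flagged as undefined", {
  m <- snp_matrix(matrix(c("A", "T", "N", "N"), nrow = 2))
  st <- compute_locus_stats(m)
  expect_false(st$undefined[1])
  expect_true(st$undefined[2])
  expect_true(is.na(st$maf[2]))
})

test_that("locus filter is strict on MAF, zero-tolerance on missing by default", {
  # L1: maf 0.25 clean -> kept; L2: maf exactly 0.15 -> dropped (strict >);
  # L3: maf 0.3 but one missing -> dropped under max_missing = 0
  calls <- cbind(L1 = c(rep("A", 15), rep("T", 5)),
                 L2 = c(rep("A", 17), rep("T", 3)),
                 L3 = c(rep("A", 13), rep("T", 6), "N"))
  m <- snp_matrix(calls, sample_ids = paste0("s", 1:20))
  expect_message(f <- filter_loci(m), "dropped 2")
  expect_equal(locus_ids(f), "L1")
  # idempotence
  expect_equal(suppressMessages(filter_loci(f))$calls, f$calls)
  # everything filtered -> explicit error
  expect_error(suppressMessages(filter_loci(m, maf_min = 0.49)), "all.*loci")
})

test_that("write/read round-trips are exact in all three formats", {
  for (seed in 1:3) {
    m <- rand_snp_matrix(6, 8, seed = seed, missing = if (seed == 1) 0 else 0.1)
    # VCF can only carry biallelic loci; use a simulated (biallelic) panel
    biallelic <- simulate_panel(sim_config(lines_per_subpop = c(3, 3),
                                           n_loci = 8,
                                           missing_rate = if (seed == 1) 0 else 0.1,
                                           seed = seed))
    biallelic$true_labels <- NULL
    for (fmt in c("matrix", "hapmap", "vcf")) {
      mm <- if (fmt == "vcf") biallelic else m
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_genotype_table(mm, f, fmt)
      back <- read_genotype_table(f, fmt)
      expect_identical(back$calls, mm$calls,
                       label = paste("round trip", fmt, "seed", seed))
    }
  }
})

test_that("hapmap output carries the standard 11-column header prefix", {
  m <- rand_snp_matrix(3, 4, seed = 1)
  f <- withr::local_tempfile(fileext = ".hmp.txt")
  write_genotype_table(m, f, "hapmap")
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(hdr[1:11],
               c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode"))
  expect_equal(hdr[-(1:11)], sample_ids(m))
})

test_that("label sidecar files round-trip true subpopulation labels", {
  m <- rand_snp_matrix(4, 3, seed = 2)
  m$true_labels <- c("a", "a", "b", "b")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(m, f)
  m2 <- rand_snp_matrix(4, 3, seed = 2)
  m2 <- read_labels(m2, f)
  expect_equal(m2$true_labels, m$true_labels)
})
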