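# Genotype table input/output and locus-level filtering.
#
# Three dialects are supported:
#   * "matrix": plain TSV/CSV, first column sample IDs, header row locus IDs.
#   * "hapmap": TASSEL .hmp.txt — 11 metadata columns then one column per
#     sample, loci in rows, single-letter homozygous calls.
#   * "vcf":    VCF v4.x with GT genotypes, biallelic SNP records only.
#
# Inbred-line convention: heterozygous calls (IUPAC ambiguity letters or
# 0/1-style VCF genotypes) are mapped to missing rather than rejected, since
# the methods here assume fully homozygous lines.

HAPMAP_META_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                      "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

# IUPAC ambiguity codes that denote heterozygous or uncertain single-letter
# calls; all map to missing under the homozygosity convention.
IUPAC_HET <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

normalize_calls <- function(x, where = "genotype table", strict = FALSE) {
  x <- toupper(x)
  x[x %in% c("-", ".", "", "NA", "NN")] <- MISSING_CALL
  # two-letter diploid calls: homozygous collapses, heterozygous -> missing
  two <- !is.na(x) & nchar(x) == 2L
  if (any(two)) {
    a <- substr(x[two], 1L, 1L); b <- substr(x[two], 2L, 2L)
    x[two] <- ifelse(a == b, a, MISSING_CALL)
  }
  x[is.na(x)] <- MISSING_CALL
  het <- x %in% IUPAC_HET
  if (any(het)) {
    if (strict)
      stop2("heterozygous/ambiguous call(s) in ", where,
            " (strict mode): e.g. '", x[which(het)[1L]], "'")
    x[het] <- MISSING_CALL
  }
  bad <- !(x %in% c(NUC_ORDER, MISSING_CALL))
  if (any(bad))
    stop2("unrecognised genotype symbol '", x[which(bad)[1L]], "' in ", where)
  x
}

#' Read a genotype table
#'
#' Reads homozygous SNP calls from one of three dialects into an
#' [snp_matrix()]. Heterozygous calls (IUPAC ambiguity letters, two-letter
#' calls with differing alleles, or VCF genotypes such as `0/1`) are recorded
#' as missing, reflecting the inbred-line assumption; set `strict = TRUE` to
#' raise an error instead. Row (sample) and column (locus) order follow the
#' file; no position sorting is performed.
#'
#' @param path path to an existing file.
#' @param format one of `"matrix"`, `"hapmap"`, `"vcf"`.
#' @param strict logical; error on heterozygous calls instead of mapping
#'   them to missing.
#' @return an `snp_matrix`.
#' @export
read_genotype_table <- function(path, format = c("matrix", "hapmap", "vcf"),
                                strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  switch(format,
         matrix = read_matrix_format(path, strict),
         hapmap = read_hapmap_format(path, strict),
         vcf = read_vcf_format(path, strict))
}

read_matrix_format <- function(path, strict = FALSE) {
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE, na.strings = NULL)
  if (nrow(dt) == 0L || ncol(dt) < 2L)
    stop2("empty genotype matrix in ", path)
  ids <- as.character(dt[[1L]])
  calls <- as.matrix(dt[, -1L, drop = FALSE])
  calls[] <- normalize_calls(calls, where = basename(path), strict = strict)
  snp_matrix(calls, sample_ids = ids, locus_ids = colnames(dt)[-1L])
}

read_hapmap_format <- function(path, strict = FALSE) {
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE, na.strings = NULL)
  if (ncol(dt) < 12L)
    stop2("HapMap file ", path, " has no sample columns ",
          "(need 11 metadata columns + samples)")
  first <- names(dt)[1L]
  if (!(first %in% c("rs#", "rs")))
    stop2("not a HapMap table (first column is '", first, "', expected 'rs#')")
  loci <- as.character(dt[[1L]])
  smp <- names(dt)[-(1:11)]
  calls <- t(as.matrix(dt[, -(1:11), drop = FALSE]))  # samples x loci
  calls[] <- normalize_calls(calls, where = basename(path), strict = strict)
  snp_matrix(calls, sample_ids = smp, locus_ids = loci)
}

read_vcf_format <- function(path, strict = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop2("no variant records in ", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt[is.na(alt)] <- "."  # vcfR reads a missing ALT ('.') as NA
  bad <- !(ref %in% NUC_ORDER) | !(alt %in% c(NUC_ORDER, ".")) |
    grepl(",", alt, fixed = TRUE)
  if (any(bad))
    stop2("VCF record ", which(bad)[1L], " (", fix[which(bad)[1L], "CHROM"],
          ":", fix[which(bad)[1L], "POS"],
          ") is not a biallelic SNP; only single-base REF/ALT records are supported")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop2("no GT genotypes in ", path)
  # phased and unphased are treated identically
  gtn <- gsub("|", "/", gt, fixed = TRUE)
  hom_ref <- gtn %in% c("0/0", "0")
  hom_alt <- gtn %in% c("1/1", "1")
  if (strict) {
    het <- !is.na(gtn) & !hom_ref & !hom_alt & !(gtn %in% c("./.", "."))
    if (any(het))
      stop2("heterozygous genotype '", gtn[which(het)[1L]],
            "' in ", path, " (strict mode)")
  }
  calls <- matrix(MISSING_CALL, nrow = nrow(gtn), ncol = ncol(gtn))
  calls[hom_ref] <- rep(ref, times = ncol(gtn))[hom_ref]
  calls[hom_alt] <- rep(alt, times = ncol(gtn))[hom_alt]
  if (any(hom_alt & rep(alt == ".", times = ncol(gtn))))
    stop2("hom-alt genotype at a record with ALT='.' in ", path)
  snp_matrix(t(calls), sample_ids = colnames(gt), locus_ids = ids)
}

#' Per-locus allele statistics
#'
#' Tallies allele counts per locus and derives the minor allele frequency
#' (MAF) and missing fraction used by [filter_loci()]. MAF is the count of
#' the second-most-frequent allele divided by the number of non-missing
#' calls; monomorphic loci have MAF 0, and loci with no non-missing calls get
#' `NA` with `undefined = TRUE`.
#'
#' @param m an `snp_matrix`.
#' @return a data frame with one row per locus: `locus_id`, allele counts
#'   (`A`, `T`, `G`, `C`), `n_called`, `maf`, `missing_fraction`, `undefined`.
#' @export
compute_locus_stats <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  calls <- m$calls
  n <- nrow(calls)
  counts <- vapply(NUC_ORDER, function(nuc) colSums(calls == nuc),
                   numeric(ncol(calls)))
  if (ncol(calls) == 1L) counts <- matrix(counts, nrow = 1L,
                                          dimnames = list(NULL, NUC_ORDER))
  n_called <- rowSums(counts)
  # second-largest allele count per locus
  second <- apply(counts, 1L, function(x) sort(x, decreasing = TRUE)[2L])
  maf <- ifelse(n_called > 0L, second / n_called, NA_real_)
  data.frame(locus_id = colnames(calls),
             counts,
             n_called = n_called,
             maf = maf,
             missing_fraction = (n - n_called) / n,
             undefined = n_called == 0L,
             row.names = NULL,
             check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Filter loci on minor allele frequency and missingness
#'
#' Retains loci whose MAF is strictly greater than `maf_min` and whose
#' missing fraction is at most `max_missing`. The defaults reproduce the
#' common inbred-panel filter of MAF > 0.15 with no missing data. The
#' boundary is strict: a locus with MAF exactly equal to `maf_min` is
#' dropped. Loci with undefined MAF (all calls missing) are always dropped.
#'
#' @param m an `snp_matrix`.
#' @param maf_min MAF threshold in `[0, 1]` (strict `>`).
#' @param max_missing maximum tolerated missing fraction in `[0, 1]`.
#' @return the filtered `snp_matrix`; errors if no locus survives.
#' @export
filter_loci <- function(m, maf_min = 0.15, max_missing = 0) {
  stopifnot(inherits(m, "snp_matrix"))
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min > 1)
    stop2("maf_min must be in [0, 1]")
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1)
    stop2("max_missing must be in [0, 1]")
  st <- compute_locus_stats(m)
  keep <- !st$undefined & st$maf > maf_min & st$missing_fraction <= max_missing
  dropped <- sum(!keep)
  message("filter_loci: dropped ", dropped, " of ", nrow(st),
          " loci (MAF > ", maf_min, ", missing <= ", max_missing, ")")
  if (!any(keep))
    stop2("all ", nrow(st), " loci removed by the MAF/missingness filter; ",
          "downstream stages need at least one locus")
  snp_matrix(m$calls[, keep, drop = FALSE], true_labels = m$true_labels)
}

#' Write a genotype table
#'
#' Writes an `snp_matrix` in any of the supported dialects such that
#' `read_genotype_table()` reproduces calls, sample IDs and locus IDs
#' exactly. For VCF output each locus may carry at most two distinct
#' alleles; the major allele is written as REF. True subpopulation labels
#' are not part of these formats; persist them separately (see
#' [write_labels()]).
#'
#' @inheritParams read_genotype_table
#' @param m an `snp_matrix`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(m, path, format = c("matrix", "hapmap", "vcf")) {
  stopifnot(inherits(m, "snp_matrix"))
  format <- match.arg(format)
  validate_snp_matrix(m)
  switch(format,
         matrix = {
           df <- data.frame(sample = sample_ids(m), m$calls,
                            check.names = FALSE, stringsAsFactors = FALSE)
           data.table::fwrite(df, path, sep = "\t", quote = FALSE)
         },
         hapmap = write_hapmap_format(m, path),
         vcf = write_vcf_format(m, path))
  invisible(path)
}

write_hapmap_format <- function(m, path) {
  calls <- t(m$calls)  # loci x samples
  alleles <- apply(calls, 1L, function(x) {
    a <- sort(unique(x[x != MISSING_CALL]))
    if (length(a) == 0L) "N/N"
    else paste(a[c(1L, min(2L, length(a)))], collapse = "/")
  })
  meta <- data.frame(`rs#` = rownames(calls), alleles = alleles,
                     chrom = "0", pos = seq_len(nrow(calls)), strand = "+",
                     `assembly#` = NA, center = NA, protLSID = NA,
                     assayLSID = NA, panelLSID = NA, QCcode = NA,
                     check.names = FALSE, stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(calls, stringsAsFactors = FALSE))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
}

write_vcf_format <- function(m, path) {
  calls <- t(m$calls)  # loci x samples
  lines <- c("##fileformat=VCFv4.2",
             "##source=snpcluster",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(calls)), collapse = "\t"))
  body <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    tab <- sort(table(x[x != MISSING_CALL]), decreasing = TRUE)
    if (length(tab) > 2L)
      stop2("locus '", rownames(calls)[i], "' has ", length(tab),
            " alleles; VCF output supports at most two")
    if (length(tab) == 0L)
      stop2("locus '", rownames(calls)[i], "' has no called alleles")
    ref <- names(tab)[1L]
    alt <- if (length(tab) == 2L) names(tab)[2L] else "."
    gt <- ifelse(x == ref, "0/0", ifelse(x == MISSING_CALL, "./.", "1/1"))
    paste(c("0", i, rownames(calls)[i], ref, alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1L))
  writeLines(c(lines, body), path)
}

#' Write or read a two-column sample/label TSV
#'
#' Companion persistence for the subpopulation labels that the genotype
#' formats cannot carry.
#' @param m an `snp_matrix` with `true_labels`.
#' @param path output path.
#' @export
write_labels <- function(m, path) {
  stopifnot(inherits(m, "snp_matrix"))
  if (is.null(m$true_labels)) stop2("snp_matrix has no true_labels to write")
  data.table::fwrite(data.frame(sample = sample_ids(m),
                                label = m$true_labels),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @return `read_labels()` returns `m` with `true_labels` attached, matched
#'   by sample ID.
#' @export
read_labels <- function(m, path) {
  stopifnot(inherits(m, "snp_matrix"))
  lab <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           colClasses = "character")
  idx <- match(sample_ids(m), lab[[1L]])
  if (anyNA(idx))
    stop2("label file ", path, " is missing sample(s): ",
          paste(utils::head(sample_ids(m)[is.na(idx)], 3L), collapse = ", "))
  m$true_labels <- lab[[2L]][idx]
  validate_snp_matrix(m)
}
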