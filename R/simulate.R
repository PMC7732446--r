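# Balding-Nichols simulation of differentiated inbred subpopulations.
#
# Per locus, an ancestral minor allele frequency is drawn uniformly from
# `ancestral_maf_range` and reflected to (0, 1) (either allele may be the
# minor one). Each subpopulation k then draws its own allele frequency
#   p_k ~ Beta(p (1-F)/F, (1-p) (1-F)/F)
# so that E[p_k] = p and Var[p_k] = F p (1-p) — the Balding-Nichols model
# with differentiation parameter F (the expected FST). At F = 0 the limit
# p_k = p is used exactly. Each inbred line draws ONE allele per locus
# (fully homozygous call, i.e. the selfing limit), and the two alleles of a
# locus are two distinct nucleotides drawn without replacement from
# {A, C, G, T} so all four letters occur across loci.

#' Simulation configuration for a structured inbred SNP panel
#'
#' Defaults emulate a real two-subpopulation maize panel: 97 + 86 fully
#' homozygous lines, 4,812 biallelic loci with ancestral MAF above 0.15,
#' no missing data, and moderate differentiation (FST 0.3) typical of two
#' well-separated heterotic groups.
#'
#' @param n_subpops number of subpopulations (>= 1).
#' @param lines_per_subpop integer vector of line counts, one per
#'   subpopulation.
#' @param n_loci number of biallelic loci.
#' @param fst differentiation parameter in `[0, 1)`.
#' @param ancestral_maf_range interval within `(0, 0.5]` from which ancestral
#'   minor allele frequencies are drawn uniformly.
#' @param missing_rate per-call probability of a missing genotype.
#' @param seed integer RNG seed; every simulated panel is reproducible
#'   from it.
#' @return a `sim_config` list.
#' @seealso [simulate_panel()]
#' @export
sim_config <- function(n_subpops = 2L,
                       lines_per_subpop = c(97L, 86L),
                       n_loci = 4812L,
                       fst = 0.3,
                       ancestral_maf_range = c(0.15, 0.5),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_subpops = as.integer(n_subpops),
              lines_per_subpop = as.integer(lines_per_subpop),
              n_loci = as.integer(n_loci),
              fst = fst,
              ancestral_maf_range = ancestral_maf_range,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  if (cfg$n_subpops < 1L) stop2("need at least one subpopulation")
  if (length(cfg$lines_per_subpop) != cfg$n_subpops)
    stop2("lines_per_subpop must have one entry per subpopulation")
  if (any(cfg$lines_per_subpop < 1L)) stop2("each subpopulation needs >= 1 line")
  if (cfg$n_loci < 1L) stop2("need at least one locus")
  if (!is.numeric(fst) || fst < 0 || fst >= 1) stop2("fst must be in [0, 1)")
  r <- cfg$ancestral_maf_range
  if (length(r) != 2L || r[1L] <= 0 || r[2L] > 0.5 || r[1L] > r[2L])
    stop2("ancestral_maf_range must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate an inbred-line SNP panel with known structure
#'
#' Draws a fully homozygous sample-by-locus nucleotide matrix under the
#' Balding-Nichols model (see [sim_config()] for the generative details)
#' with true subpopulation labels attached, so the whole inference pipeline
#' can be exercised and scored without real data.
#'
#' @param cfg a [sim_config()].
#' @return an [snp_matrix()] with `true_labels` set to `"pop1"`, `"pop2"`,
#'   ...; sample IDs encode the subpopulation of origin.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    L <- cfg$n_loci
    K <- cfg$n_subpops
    n <- sum(cfg$lines_per_subpop)
    # ancestral frequency of allele 1, reflected so either allele is minor
    maf <- stats::runif(L, cfg$ancestral_maf_range[1L], cfg$ancestral_maf_range[2L])
    p <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)
    # subpopulation frequencies
    F <- cfg$fst
    pk <- matrix(0, nrow = K, ncol = L)
    for (k in seq_len(K)) {
      pk[k, ] <- if (F == 0) p else
        stats::rbeta(L, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
    # allele letters: two distinct nucleotides per locus
    a1 <- character(L); a2 <- character(L)
    for (j in seq_len(L)) {
      pair <- sample(NUC_ORDER, 2L)
      a1[j] <- pair[1L]; a2[j] <- pair[2L]
    }
    pop <- rep(seq_len(K), times = cfg$lines_per_subpop)
    # one allele draw per line per locus (selfing limit: fully homozygous)
    u <- matrix(stats::runif(n * L), nrow = n)
    is1 <- u < pk[pop, , drop = FALSE]
    calls <- matrix(ifelse(is1, rep(a1, each = n), rep(a2, each = n)), nrow = n)
    if (cfg$missing_rate > 0)
      calls[stats::runif(n * L) < cfg$missing_rate] <- MISSING_CALL
    labels <- paste0("pop", pop)
    ids <- paste0("pop", pop, "_", sprintf("%03d",
                  unlist(lapply(cfg$lines_per_subpop, seq_len))))
    snp_matrix(calls, sample_ids = ids,
               locus_ids = sprintf("snp%0*d", nchar(L), seq_len(L)),
               true_labels = labels)
  })
}

#' Hudson-style FST estimate between subpopulations
#'
#' Ratio-of-sums Hudson estimator with finite-sample correction: per locus,
#' with sample allele frequencies \eqn{\hat p_1, \hat p_2} over \eqn{n_1,
#' n_2} haploid lines,
#' \deqn{N = (\hat p_1 - \hat p_2)^2 - \frac{\hat p_1(1-\hat p_1)}{n_1 - 1}
#'        - \frac{\hat p_2(1-\hat p_2)}{n_2 - 1}, \quad
#'       D = \hat p_1 (1-\hat p_2) + \hat p_2 (1-\hat p_1),}
#' and the estimate is \eqn{\sum N / \sum D} over loci. With more than two
#' subpopulations the mean over all pairs is returned. Serves as the
#' simulator's self-check: on Balding-Nichols panels the estimate recovers
#' the configured `fst` up to sampling noise.
#'
#' @param m an [snp_matrix()].
#' @param labels subpopulation labels (defaults to `m$true_labels`).
#' @return the FST estimate (clamped to `[0, 1]` only by the data, not
#'   artificially).
#' @export
empirical_fst <- function(m, labels = m$true_labels) {
  stopifnot(inherits(m, "snp_matrix"))
  if (is.null(labels)) stop2("subpopulation labels are required")
  labels <- as.character(labels)
  if (length(labels) != n_samples(m))
    stop2("labels length does not match sample count")
  pops <- unique(labels)
  if (length(pops) < 2L) stop2("need >= 2 subpopulations")
  if (any(table(labels) < 2L)) stop2("need >= 2 lines per subpopulation")
  # reference allele per locus: the lexicographically first observed allele
  calls <- m$calls
  refa <- apply(calls, 2L, function(x) {
    a <- sort(unique(x[x != MISSING_CALL]))
    if (length(a) == 0L) NA_character_ else a[1L]
  })
  if (all(is.na(refa))) stop2("panel is entirely missing")
  poly <- !is.na(refa)
  pairs <- utils::combn(pops, 2L, simplify = FALSE)
  ests <- vapply(pairs, function(pr) {
    f <- lapply(pr, function(g) {
      sub <- calls[labels == g, poly, drop = FALSE]
      called <- sub != MISSING_CALL
      nk <- colSums(called)
      ph <- colSums(sub == rep(refa[poly], each = nrow(sub)) & called) /
        pmax(nk, 1L)
      list(p = ph, n = nk)
    })
    ok <- f[[1L]]$n > 1L & f[[2L]]$n > 1L
    p1 <- f[[1L]]$p[ok]; p2 <- f[[2L]]$p[ok]
    n1 <- f[[1L]]$n[ok]; n2 <- f[[2L]]$n[ok]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    keep <- den > 0
    if (!any(keep)) stop2("panel is monomorphic between ",
                          pr[1L], " and ", pr[2L])
    sum(num[keep]) / sum(den[keep])
  }, numeric(1L))
  mean(ests)
}
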