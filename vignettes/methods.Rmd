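---
title: "Methods: autoencoder-based population structure inference for inbred SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoencoder-based population structure inference for inbred SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snpcluster` infers population genetic structure from panels of fully
homozygous SNP genotypes by unsupervised learning: numeric encoding of the
nucleotide calls, non-linear (deep autoencoder) or linear (PCA)
dimensionality reduction, clustering in the reduced space, internal
validity indexes to choose the number of clusters, and a cross-tab score
against known subpopulations when labels exist. This vignette documents the
model, every tunable that matters, the numerical conventions, and what the
test evidence does and does not show.

## Data model and assumptions

The genotype container is a sample × locus character matrix of single
nucleotide letters. The central assumption is **homozygosity**: the method
targets inbred lines (repeatedly selfed genotypes), so a single letter per
call is a faithful representation and no Hardy–Weinberg-style genotype
frequencies enter anywhere. Heterozygous input (IUPAC ambiguity codes,
two-letter calls, VCF `0/1` genotypes) is mapped to missing on read rather
than rejected, because residual heterozygosity in real inbred panels is
sparse genotyping noise, not signal; `strict = TRUE` turns the mapping into
an error for users who want to audit their input. Missing data is the `N`
sentinel (`-` and `.` are accepted on input).

Loci are filtered before analysis: minor allele frequency strictly greater
than `maf_min` (default 0.15) and missing fraction at most `max_missing`
(default 0). The strict inequality means boundary loci (MAF exactly 0.15)
are dropped. MAF is the count of the second most frequent allele over
non-missing calls, so monomorphic loci score 0 and are always removed at
any positive threshold.

## Encodings

Two numeric representations are compared throughout:

* **One-hot** (`one_hot_encode()`): each call becomes a 4-channel indicator
  block in the fixed channel order (A, T, G, C) — A → `[1,0,0,0]`,
  T → `[0,1,0,0]`, G → `[0,0,1,0]`, C → `[0,0,0,1]`. The order is a
  convention carried consistently by the encoder, decoder and loss; it is
  deliberately not alphabetical. Missing calls are the all-zero block.
  Width is 4 L for L loci, locus-major.
* **Label encoding** (`label_encode()`): A:0, T:1, G:2, C:3, the classical
  baseline. It imposes an artificial ordinality (A < T < G < C), which is
  exactly why it serves as the comparison point for the learned
  representation. Missing becomes the reserved code −1 and downstream
  stages refuse matrices containing it, so the user must filter first.

## The autoencoder

The reduction at the heart of the package is a symmetric feed-forward
autoencoder on the one-hot matrix:

```
4L  ->  2000  ->  700  ->  40  ->  700  ->  2000  ->  4L
```

ReLU activations on all hidden layers including the 40-unit bottleneck,
and a **per-locus 4-way softmax** output head: the reconstruction of every
locus is a probability distribution over {A, T, G, C}. The loss is the
masked categorical cross-entropy

$$\mathcal{L} = \frac{1}{|\mathcal{O}|} \sum_{(i,\ell) \in \mathcal{O}}
  \; -\sum_{c \in \{A,T,G,C\}} y_{i\ell c} \log \hat y_{i\ell c},$$

where $\mathcal{O}$ is the set of observed (non-missing) sample–locus
pairs: all-zero blocks contribute no target mass and are excluded from the
denominator, so missing data neither drags the loss toward a constant nor
biases the gradients. A per-channel sigmoid head with binary cross-entropy
is available (`loss = "sigmoid_bce"`) but the softmax head respects the
one-hot block structure and is the default.

Training is Adam (moment decays 0.9/0.999, $\epsilon = 10^{-8}$) at step
size 0.001, minibatches reshuffled each epoch from an integer seed. Weights
are initialised He-uniform ($U(\pm\sqrt{6/d_{in}})$, appropriate for ReLU)
from a seed, biases at zero. Two runs with the same seeds produce
bit-identical loss histories; this determinism is tested, as is the
analytic gradient against central finite differences (relative error below
$10^{-5}$), which is the advantage of implementing the network natively in
matrix algebra rather than binding a deep-learning runtime. The only
compiled code is a small in-place Adam kernel; all tensor math is
BLAS-backed base R.

Tunables and defaults:

* `encoder_widths = c(2000, 700)`, `bottleneck_dim = 40` — the two-layer
  configuration that minimised reconstruction loss for a 183 × 4,812 maize
  panel among depths 1–4; `depth_search()` re-runs that comparison on any
  dataset, with candidate widths on a geometric schedule between the input
  width and the bottleneck. For inputs narrower than 2,000 units the
  pipeline substitutes the geometric schedule automatically.
* `epochs = 200`, `batch_size = 32` — conservative defaults for full-size
  panels. Early stopping (patience 20 on the training loss) is available
  but off by default, so default runs are exactly reproducible in length.
* `learning_rate = 0.001` — Adam step size; divergence aborts with a
  diagnostic rather than returning NaN weights.

The embedding used by all downstream stages is the bottleneck activation
matrix (n × 40 by default). Because the bottleneck is ReLU, embeddings are
nonnegative; clustering uses Euclidean geometry, for which this is
immaterial.

## PCA baseline

`pca_fit()` performs SVD on the column-centred (not scaled) one-hot matrix.
The default embedding width equals the bottleneck (40) for a like-for-like
comparison with the autoencoder. Component signs are fixed by the
convention that each component's largest-magnitude loading is positive,
making fits bit-reproducible. Explained variances are validated against a
brute-force covariance eigendecomposition in the tests. Label-encoded
input is accepted with a warning (the ordinality caveat above).

## Clustering

* **K-means** is implemented natively: k-means++ seeding, Lloyd iterations
  to an assignment fixed point (cap 300), 10 restarts by default with the
  best within-cluster sum of squares (WCSS) kept. The WCSS after every
  update is recorded and asserted non-increasing — a broken monotone trace
  aborts the run as an internal error. Empty clusters are repaired by
  reassigning the point farthest from its centre. On all small instances
  (n ≤ 8, K = 2) the tests verify the result equals the global optimum
  found by exhaustive partition enumeration.
* **Hierarchical clustering** delegates to `stats::hclust` (Lance–Williams
  agglomeration on Euclidean distances); `"ward"` maps to `ward.D2`, the
  squared-Euclidean Ward criterion, which is the default linkage because
  the embedding geometry is Euclidean. Labels are cut from the merge tree;
  the merge history (pairs + heights) is returned and heights are
  non-decreasing for the monotone linkages.

The linkage and the K-means initialisation are both unreported in the
study this design follows; ward + k-means++ with 10 restarts are this
package's choices, so index magnitudes on real data are comparable only
qualitatively.

## Validity indexes and choosing K

The silhouette coefficient and Davies–Bouldin index are computed in the
same embedding space that was clustered — including for the label-encoding
baseline, where they are computed on the raw integer matrix (the baseline
has no reduced space; this is this package's reading of an underspecified
point). Conventions: silhouette of a singleton-cluster member is 0; points
with $a = b = 0$ (identical points split across clusters) score 0;
Davies–Bouldin errors on coincident centroids rather than dividing by
zero. Both implementations are checked against literal brute-force
oracles to $10^{-12}$ on every instance with n ≤ 12, and both are exactly
invariant to translation, rotation and uniform scaling of the embedding.

`scan_k()` tabulates both indexes over K = 2…9 (the conventional range for
a panel expected to split into a handful of subpopulations) and
`select_k()` picks argmax-SC (default) or argmin-DBI, breaking ties toward
the smaller K — the more parsimonious structure. When the two criteria
disagree the selection is flagged, not silently resolved; silhouette is
the default selector.

## Assignment accuracy

`cross_tab()` counts cluster × subpopulation co-occurrences;
`match_clusters()` finds the injective cluster → subpopulation map
maximising the matched total, by an exact dynamic program over column
subsets (equivalent to the Hungarian algorithm at these sizes, capped at
12 × 12; identical to majority matching in the 2 × 2 case). Ties prefer
the identity-order mapping. Unmatched clusters (K > G) contribute zero.
%CA is 100 × matched / n, reported raw and rounded half-up to integer
percent (`round()`'s banker's rounding would turn 95.5 into 96 but 92.5
into 92, so a dedicated half-up rule is used — matching how whole-percent
accuracies are conventionally quoted).

## The simulator: what it emulates, and what it does not

`simulate_panel()` draws panels under the Balding–Nichols model: per locus
an ancestral minor allele frequency uniform on (0.15, 0.5] (mirroring a
post-filter panel), reflected so either allele may be minor; subpopulation
frequencies $p_k \sim \mathrm{Beta}\big(p\tfrac{1-F}{F},
(1-p)\tfrac{1-F}{F}\big)$, so $\mathbb{E}[p_k] = p$ and
$\mathrm{Var}[p_k] = F\,p(1-p)$ with $F$ the expected FST (at $F = 0$ the
limit $p_k = p$ is used exactly); each line draws one allele per locus —
the selfing limit, giving fully homozygous calls; the two alleles of each
locus are distinct nucleotides drawn without replacement from {A, C, G, T}
so the full one-hot alphabet is exercised. Defaults emulate a real maize
diversity panel: 97 + 86 lines, 4,812 loci, no missing data, and FST 0.3 —
a differentiation typical of well-separated heterotic groups (dent vs
popcorn germplasm), chosen once as the package's reference condition.
`empirical_fst()` (Hudson-type ratio-of-sums estimator with finite-sample
correction) closes the loop: simulated panels recover the configured FST
within sampling noise, and the estimate is tested at ±0.05 of the target
at 120 lines × 2,000 loci.

What the simulator deliberately omits: linkage (loci are independent, no
recombination map or LD structure), admixed individuals, genotyping-error
models beyond uniform missingness, and selection. Passing the end-to-end
tests therefore shows the pipeline recovers **island-model structure in
unlinked loci**; it does not certify behaviour under strong LD, admixture
gradients, or batch-confounded missingness, all of which real GBS panels
can contain.

## Problem sizes used by the verification suite

The end-to-end study behind the acceptance checks runs five replicate
panels of 60 + 60 lines × 1,000 loci at FST 0.3 (and five at FST 0 as the
chance-regime control). At this panel size the autoencoder is trained for
50 epochs with minibatches of 60: the training loss is flat after roughly
30 epochs on these panels, so the schedule is past convergence while
keeping a ten-replicate study tractable on a single CPU. The package
defaults (200 epochs, batch 32) remain the recommendation for full-size
panels. Expected behaviour at these conditions, verified by the tests: the
silhouette scan selects K = 2 in at least four of five replicates, both
DeepAE-HC and PCA-HC recover ≥ 95% of individual assignments (median), at
FST 0 accuracy collapses below 65% (chance regime for a balanced 2 × 2
cross-tab is ~50–60%), and the silhouette at K = 2 orders the
representations DeepAE ≥ PCA > label encoding.

## Visualisation

`tsne_embed()` is a deterministic exact $O(n^2)$ t-SNE (perplexity
bisection to $10^{-5}$, early exaggeration ×4 for 100 iterations, momentum
0.5 → 0.8 at iteration 250, adaptive gains, seeded Gaussian
initialisation at σ = 10⁻⁴) with the interface conventions of the standard
implementations: perplexity 30, 1,000 iterations, learning rate 200, and a
feasibility bound perplexity < (n − 1)/3. Panels here are hundreds of
lines, so the quadratic exact algorithm is preferable to a Barnes–Hut
approximation — it is simpler, seeded-deterministic, and its output
contract (n × 2, finite, within-group distances smaller than between-group
on separable panels) is tested. `pca_scatter()` exposes the first two PC
scores; on separable two-population panels the split aligns with PC1.

## Known limitations

* The autoencoder trains on all rows (no train/validation split), which is
  standard for unsupervised embedding but means `depth_search()` should be
  given a `holdout` fraction when used for genuine model comparison.
* Index magnitudes depend on unstated conventions of other
  implementations (linkage variant, K-means initialisation), so
  comparisons to published tables are qualitative; the orderings and
  selected K are the reproducible quantities.
* The optimal-assignment evaluation is capped at 12 clusters ×
  12 subpopulations.
* Very small architectures can land in dead-ReLU local minima for some
  initialisation seeds (all bottleneck units inactive, loss plateau); at
  realistic widths this has not been observed. Re-seeding, a sigmoid head,
  or a smaller learning rate are the remedies.
* t-SNE coordinates are for visual inspection only and are never fed back
  into clustering.
* VCF output requires biallelic loci (at most two observed alleles per
  locus) and writes the major allele as REF.
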