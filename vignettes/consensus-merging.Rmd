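---
title: "Consensus cluster merging: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus cluster merging: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustermerge)
```

## The problem

Unsupervised clustering of single-cell RNA-seq data (and of high-dimensional
data generally) faces a resolution/replicability trade-off: the more clusters
a method is asked to find, the less likely each of them is to reappear when
the analysis is repeated with a different algorithm, different tuning
parameters, or a related dataset. Different reasonable pipelines therefore
produce partitions that disagree in their fine structure while agreeing on a
coarser shared structure.

`clustermerge` takes several partitions of the same observations and merges
clusters *within* each partition, greedily, so as to maximize the agreement
*between* partitions. The premise is that structure all inputs can express
after coarsening is the structure worth keeping; resolution beyond that point
is method idiosyncrasy.

## The objective and the greedy update

Agreement between two partitions $P_1, P_2$ is measured by the normalized
mutual information

$$\mathrm{NMI}(P_1, P_2) =
  \frac{2\,\bigl(H(P_2) - H(P_2 \mid P_1)\bigr)}{H(P_1) + H(P_2)},$$

where $H$ is the Shannon entropy of the cluster-membership distribution and
the conditional entropy is computed from the contingency table of the two
partitions. The numerator equals twice the mutual information, so the measure
is symmetric, relabeling-invariant, 1 exactly for identical partitions, and
0 for independent ones. For $R$ partitions the objective is the mean NMI over
all $\binom{R}{2}$ pairs.

At each step the algorithm scores every candidate — every pair of clusters
$(i, j)$ within every partition $r$ — by the summed change in agreement with
the other partitions,

$$\Delta(r, i, j) = \sum_{s \neq r}
  \mathrm{NMI}(P_r^{\,i \cup j}, P_s) - \mathrm{NMI}(P_r, P_s),$$

and executes the best merge. Because each step merges a single pair in a
single partition, and merging everything into one cluster would first have to
pass through steps that *decrease* agreement, the procedure does not collapse
to the degenerate all-in-one optimum: it halts at the resolution where the
inputs genuinely agree. The adjusted Rand index can be substituted as the
merging criterion (`metric = "ari"`).

## Numerical and design choices

* **Log base.** Entropies are in nats. NMI is a ratio, so the choice has no
  effect on it.
* **Degenerate NMI.** Two single-cluster partitions have NMI 1 (they are
  identical); one single-cluster partition has NMI 0 against any non-trivial
  partition (zero mutual information). This is continuous with the
  non-degenerate limit and makes merging toward one cluster maximally
  unattractive.
* **Stopping rule.** A merge is executed only when its summed improvement is
  strictly positive; the algorithm stops when the best candidate is $\le 0$.
  Zero-gain merges would be arbitrary coarsenings and would break the strict
  monotonicity of the recorded trajectory.
* **Tie-breaking.** The argmax is resolved deterministically: smallest
  partition index, then the smallest cluster pair in canonical
  (first-appearance) order. Results are therefore reproducible and
  independent of any parallel evaluation schedule.
* **Merged-cluster naming.** The canonical-first id of the pair survives.
* **Incremental updates.** Pairwise contingency tables are cached; a merge
  collapses two rows of each table involving the merged partition, and
  candidate scores are recomputed from row and column sums only — never by
  re-scanning the $n$ observations. The results are contractually
  bit-identical to full recomputation, which the test suite enforces against
  an independent brute-force implementation.
* **Unclustered observations.** A sentinel label (default `"-1"`) marks
  observations excluded from every contingency table, entropy, and merge.
* **Early stopping.** `stop_fraction` (in $[0,1]$) returns the earliest
  recorded state whose cumulative gain in mean NMI reaches that fraction of
  the total gain; 1 is the natural stopping point.
* **Cost.** Each step scores $\sum_r \binom{k_r}{2}$ candidates at
  $O(R\,k_{\max})$ apiece from the cached tables. Work grows quadratically
  in the number of partitions; in practice $R = 3$ inputs give most of the
  benefit.

## The baseline mergers

Two hierarchical mergers, widely used to reduce cluster counts, serve as
comparators.

* **Dist** computes, for each cluster, the medoid — the gene-wise median of
  $\log(\mathrm{count}+1)$ over its cells — builds an agglomerative tree on
  Euclidean distances between medoids, and merges bottom-up in the tree's
  join order. Left to itself it merges to a single cluster;
  `m_dist = n_merges` or, when companion partitions are supplied, the state
  maximizing mean NMI against them, provides the stopping point.
* **DE** merges the candidate pair with the smallest fraction of
  differentially expressed genes while that fraction is below a threshold
  $\alpha$ (default 0.05). Genes are tested on $\log(\mathrm{count}+1)$
  values with limma's moderated t-test and Benjamini–Hochberg adjustment at
  FDR 0.05 — the standard empirical-Bayes machinery for this task, which
  shares its model family with the count simulator below, a deliberate
  property of the benchmark (it gives the DE merger an a priori advantage
  that the consensus merger does not enjoy).

Where the literature leaves details open, these choices were made: the
medoid tree uses average linkage (symmetric and stable; single and complete
are available), and DE candidates are restricted to cherries of the medoid
tree, rebuilt after every merge (an all-pairs mode is available behind
`candidates = "all"`). Genes with no variance anywhere get $p = 1$; groups
with fewer than two cells are tolerated because the moderated variance pools
information across genes, and are flagged with a warning.

## Evaluation utilities

`truth_curve()` scores the evolving partition against a reference labeling
at every state of a merge trajectory; `curve_auc()` summarizes the curve by
its trapezoidal area over the cluster-count axis, min–max normalized to
$[0,1]$ so that a constant curve of value $v$ has AUC $v$ and paths of
different lengths are comparable. Because the consensus merger stops early
while the baselines continue to one cluster, `extend_to` extends a curve
horizontally at its final score down to a comparator's resolution before
integrating, so all methods are integrated over the same range. The
cluster-count axis and this extension convention are this package's own
definitions — the AUC is only used for relative comparisons between methods
run on the same data.

`avg_silhouette()` / `select_output()` implement the usual
average-silhouette-width heuristic for choosing one of the merged partitions.
The silhouette is computed in a user-supplied embedding; for counts, the
documented default pipeline is depth scaling, $\log1p$, the 500 most variable
genes, and 10 principal components (`embed_counts()`). The heuristic usually
selects a good partition but is known to fail on some real datasets; it is a
convenience, not a guarantee.

## What the simulators emulate

`simulate_gauss_grid()` draws isotropic unit-variance bivariate normal
components on a regular grid (default $3 \times 3$, 100 points each, centers
5 sd apart) — a testbed where the true resolution is unambiguous.

`simulate_counts()` emulates the hierarchical generative model of
Splatter-style single-cell simulators with a reduced parameter set: gene
base means from a Gamma distribution; per-group log-normal fold changes
applied to a `de_prob` fraction of genes; per-cell log-normal library-size
factors; negative binomial counts. Defaults (5000 cells, $10^4$ genes, 30
groups, `de_prob = 0.3`, `de_fc_sigma = 1`, `libsize_sigma = 0.25`,
`dispersion = 0.4`) were fixed once as a well-separated regime: strong
enough that standard clustering of the full data is nearly perfect, which is
the regime in which merging methods are meaningfully compared. Separation is
monotone in `de_prob` and `de_fc_sigma`, so harder regimes are one argument
away. The emulator deliberately omits Splatter's paths, batches, and
explicit dropout; none of these interact with the merging logic under test.

Over-clustering inputs come from `over_cluster()`: k-means or hierarchical
clustering (complete linkage by default — the `hclust` default — with the
linkage exposed) run with more clusters than groups. For count data the
`tsne_like` embedding is a k-nearest-neighbor-graph Fruchterman–Reingold
layout (`graph_embed()`): like t-SNE/UMAP, and unlike any linear 2-D
projection, it can separate dozens of well-separated groups in two
dimensions, so the "2-D embedding + k-means" input is informative rather
than degenerate; it is deterministic for a fixed seed. A linear 2-PC
projection was rejected here because it overlaps most of the 30 groups and
turns that input into noise, which merging then rightly cannot fix.

## What passing tests do and do not show

The simulations have clean group structure, independent genes, and no batch
effects, doublets, or ambient contamination. Results on them demonstrate the
correctness of the algorithms and the internal consistency of the benchmark
— not performance on real tissue data. Two further limits are worth stating
plainly, because the test suite measures them:

* At grid spacing 5 sd, k-means with $k = 20$ places some sum-of-squares
  optimal centroids *between* components, so the input partition itself has
  a best-achievable coarsening ARI of roughly 0.91–0.96. The merger reaches
  that ceiling (to within ~0.01), but no merging method can exceed it: a
  merger can only union input clusters, never split them. Recovered cluster
  counts are 9 for about half the seeds and 10–11 otherwise.
* After removing 90% of cells (~16 cells per group), input quality drops for
  some seeds, and merged quality — again at the input ceiling — drops with
  it. Retention of the full-data merged ARI ranges from ~75% to ~99% across
  seeds under the fixed default regime.

Problem sizes used by the heavier test suites, chosen as the smallest sizes
at which the respective effects are stable: the stopping-rule comparison
runs on 1000 cells, 2500 genes, 12 groups, $k = 25$ inputs; the
variance-reduction suite on 10 seeds of 600 cells, 1200 genes, 8 groups,
$k = 16$; the downsampling benchmark at the full 5000-cell scale.

## A short worked example

```{r example, eval = FALSE}
sim <- simulate_gauss_grid(seed = 1)
km <- over_cluster(sim, "kmeans", k = 20, seed = 1)
hc <- over_cluster(sim, "agglomerative", k = 20)
res <- consensus_merge(partition_set(list(km, hc)))
head(res$history$steps)
vapply(res$merged$partitions, n_clusters, integer(1))
```

Each history row records one merge (partition, pair, improvement, mean NMI
after); the trajectory is strictly increasing, and the final partitions are
coarsenings of the inputs on which no single within-partition merge can
raise the mean pairwise NMI further.
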