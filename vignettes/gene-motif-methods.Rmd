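---
title: "Gene-motif subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-motif subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cancer cohorts have been subtyped either by *which* genes are recurrently
mutated or by *how* they are mutated (the proportions of mutational
processes, summarized as trinucleotide signatures). `genemotif` implements
a pipeline that combines the two: its unit of analysis is the
**gene-motif**, a compound feature pairing a gene with one of the 96
strand-collapsed single-base substitution classes. A sample is positive
for feature `(g, c)` when it carries at least one somatic point mutation
of class `c` inside the body of gene `g`. The same gene can then
distinguish two subtypes that both mutate it — but in different sequence
contexts.

The pipeline stages are:

1. **Annotation** — each SNV is assigned its trinucleotide context from
   the reference (always read on the + strand, then pyrimidine-collapsed,
   so the class namespace is strand-symmetric and has exactly 96 members)
   and all gene bodies overlapping its position.
2. **Gene significance** — per gene, the statistic is $k$, the number of
   *distinct* samples with a mutation in the gene. A single negative
   binomial is fitted to the pooled $k$ across genes and each gene gets
   the upper-tail probability $P(X \ge k)$; genes with $p < 0.01$
   (strict) are retained.
3. **Gene-motif significance** — within the significant genes the same
   construction is applied to per-(gene, class) distinct-sample counts,
   with a beta-binomial null $\Pr(X = i) = \binom{n}{i} B(i+\alpha,\,
   n-i+\beta)/B(\alpha, \beta)$ over cohort size $n$.
4. **Clustering** — samples are clustered on the binarized significant
   gene-motif matrix by recursive model-based clustering (below).
5. **Characterization** — subtype-vs-rest Fisher scans for genes,
   lncRNAs, transcripts and gene-motifs; per-subtype motif preferences;
   consequence-type tables; coding-vs-lncRNA mutational load; a generic
   hypergeometric over-representation test against user gene sets.
6. **Signatures** — per-sample 96-channel catalogs factorized by KL-NMF
   with stability-based selection of the signature count and Pearson
   matching against a user-supplied reference matrix.
7. **Survival** — Kaplan–Meier curves per subtype and the $k$-group
   log-rank test, plus clinical composition summaries.

# Distributional nulls and their estimation

The candidate count laws are screened with a Cullen–Frey
skewness–kurtosis diagnostic (with bootstrap, default 100 resamples) and
ranked by the Cramér–von Mises statistic
$\omega^2 = \tfrac{1}{12m} + \sum_i (F(x_{(i)}) - \tfrac{2i-1}{2m})^2$
evaluated at each fitted CDF. Both are *reports*; the pipeline's defaults
(negative binomial for genes, beta-binomial for gene-motifs) encode the
standard outcome of that screen for overdispersed mutated-sample counts.

Parameterizations. The negative binomial uses $(r, p)$ with pmf
$\binom{i+r-1}{r-1} p^r q^i$ on $i = 0, 1, \dots$ and mean $rq/p$; $r$ is
profiled by 1-D maximum likelihood with the mean fixed at the sample mean
(its MLE), initialized at the method-of-moments value. The beta-binomial
is optimized over $(\log\alpha, \log\beta)$ by Nelder–Mead from a
method-of-moments start. Degenerate inputs are refused (constant counts)
or demoted with a warning (no overdispersion: Poisson/binomial fallback).
Tail probabilities are computed from the survival function (negative
binomial) or as a direct sum of positive pmf terms (beta-binomial), which
is free of the cancellation that $1 - \mathrm{CDF}(k-1)$ suffers in thin
tails; the unit tests pin both to brute-force summation at $10^{-10}$.

**Trimmed background fits.** The pooled count histogram mixes the
background bulk with the very features the test is meant to flag. With
two free parameters, an untrimmed maximum-likelihood beta-binomial
absorbs that enriched upper tail by driving $\alpha \to 0$, producing a
fat-tailed null in which no feature is ever surprising — the enriched
features would mask themselves. Both background fits therefore exclude
the top 5% of counts (`trim = 0.05`, settable to 0); P-values are then
evaluated for *all* features against the bulk-estimated null. This is the
same logic by which covariate-based driver-gene methods estimate their
background from presumed passengers. The gene-level fit additionally
pools coding and lncRNA genes (the selection is reported per biotype),
which roughly doubles the background mass behind the fit.

No multiple-testing correction is applied to the significance *call*
(the threshold is raw $p < 0.01$, strict); Benjamini–Hochberg q-values
are reported alongside for transparency.

# Recursive clustering

Each node is processed identically:

1. restrict to features mutated in 5%–95% of the node's samples
   (`min_feature_fraction`; binary matrices only) — features below a
   node's 5% line reflect the sporadic background rate, not cluster
   structure at that node's scale;
2. standardize the remaining columns;
3. project onto the node's `n_pcs` leading principal components
   (default 1);
4. fit Gaussian mixtures over component counts `1:max_components`
   (default 9) across the configured covariance families, select by BIC;
5. apply the meaningfulness rule: the split is accepted only if at least
   two children reach `min_cluster_fraction` (default 1%) of the *whole
   cohort*; smaller children are outliers, merged into the Mahalanobis-
   nearest accepted sibling;
6. validate accepted siblings pairwise: a pair that the same analysis,
   run on the pair alone, does not recognize as two clusters is one
   over-segmented cluster and is re-merged (mixture components are not
   clusters per se; merging criteria of this kind are standard for
   model-based clustering);
7. recurse into each surviving child until no split survives or
   `max_depth` (default 4) is reached.

The per-node projection (step 3) is the load-bearing design choice, and
it was forced by an identifiability argument: BIC over the full feature
matrix is scale-invariant — the likelihood gain and parameter penalty of
refining a cluster into subclusters are essentially the same whether the
refinement is proposed at the root or inside the cluster — so a
full-dimensional search either resolves everything at the first level or
nothing at any level; it cannot produce the coarse-first, fine-later
behavior that motivates multi-level clustering. Projecting each node onto
its own dominant principal direction(s) breaks that symmetry honestly:
at the cohort level the leading direction is the deepest split of the
whole cohort, and only once a cluster is isolated does *its* leading
direction expose the next split. This is principal-direction divisive
partitioning with a Gaussian-mixture/BIC decision at each node.

Labels `SC1..SCm` are assigned deterministically (first-level branch
order, then decreasing leaf size). PCA is also exposed separately
(`pca_project`) for feature inspection; the clustering uses its own
per-node projections, not that utility.

# The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
with planted ground truth written to a sidecar the pipeline never reads.
Defaults define the study conditions: 533 samples in seven subtypes of
sizes 44/137/64/205/13/49/21, grouped into super-clusters
{1,2,3,4} and {5,6,7}; 500 coding and 500 lncRNA genes on a 4 × 450 kb
toy reference; 30 enriched gene-motifs per subtype carried by members
with probability 0.8 and non-members with probability 0.02.

Choices the generator had to make beyond those conditions, and why:

* **Driver pool (40 coding genes, cycled across subtypes).** Planted
  gene-motifs draw their genes from a shared pool so that the same gene
  hosts different motif contexts in different subtypes — the phenomenon
  the gene-motif concept exists to exploit — and so that every planted
  gene accumulates enough mutated samples to clear gene-level
  significance regardless of its subtypes' sizes.
* **Driver background load (negative binomial, mean 150, size 10,
  vs mean 8, size 1.5 for background genes).** Frequently mutated genes
  are frequently mutated everywhere, not only at their enriched
  contexts; this populates the drivers' 96 channels the way real highly
  mutated genes populate theirs, and gives the pooled beta-binomial fit
  a genuine background bulk.
* **Super-cluster features (30 per super-cluster at probability 0.9).**
  Shared features across sibling subtypes make the planted hierarchy
  genuinely two-level: the cohort's dominant contrast is the
  super-cluster split, each super-cluster's dominant contrast is its
  subtype split.
* **Hyper-mutated subtype (index 5, weight 5).** Members absorb extra
  background mutations in non-driver genes only, so hypermutation shows
  up in mutational load without contaminating planted channels.
* **Clinical defaults.** Sex, country, age and exponential survival
  hazards differ by subtype (one subtype is all-Chinese, one has a
  markedly better and one a markedly worse outcome, one skews older),
  at plausible magnitudes, so that the clinical summaries and the
  log-rank test have planted contrasts to find. Censoring is uniform on
  (0, 2000) days.

What the generator does *not* emulate: regional mutation-rate
covariates (replication timing, chromatin), indels and structural
variants, transcript splicing structure beyond nested intervals, and
linkage between motif classes and biological processes. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's statistical
machinery — not that real tumor cohorts satisfy its assumptions.

A note on cohort size: the generator's default 533 equals the sum of the
default subtype sizes; configurations with other totals (e.g. 536) are
one argument away, but then the subtype sizes must be respecified to
match.

# Signatures

Catalogs count each distinct mutation once per sample (a mutation
overlapping several genes is one event), genome-wide by default with a
gene-restricted option. Factorization is multiplicative-update NMF under
the generalized Kullback–Leibler objective (the Poisson-count choice),
best of `n_restarts` random starts. The signature count is chosen by
restart stability: per candidate $k$, every restart's signatures are
matched to the best restart's by greedy cosine similarity and the
resulting signature clusters are scored by mean silhouette under cosine
distance; the chosen $k$ is the largest candidate with stability at or
above 0.8, with the full stability and reconstruction-error curves
returned so the user can override. Reference matching reports the full
Pearson matrix, a greedy pairing, and flags reference signatures that a
two-signature linear combination explains substantially better than any
single extracted signature. Catalog bootstrap resampling is deliberately
omitted at this scale.

# Numerical and procedural conventions

* Coordinates are 1-based inclusive throughout (GTF native; BED
  converted on import). A mutation in $k$ overlapping genes counts in
  all $k$ (switchable to longest-only). Context is always read from the
  + strand and collapsed; gene strand never affects motif naming.
* Chromosome-edge positions have no context: excluded from motif-level
  analyses, retained in gene-level counts.
* Two-sided Fisher P-values follow the point-probability rule; the
  reported odds ratio is the sample odds ratio $ad/bc$ with `Inf` when
  only $bc = 0$ and `NA` for empty margins.
* Kaplan–Meier ties follow the simultaneous-event convention;
  Greenwood's formula supplies the variance. Log-rank results below
  $10^{-4}$ are flagged, never filtered.
* All stochastic steps take explicit seeds; identical seeds give
  byte-identical outputs.

# Problem sizes used in the test suite

The unit suite exercises a 180-sample, 250-gene planted cohort; the
end-to-end checks run the default 533-sample cohort once and reuse it
across tests; signature-recovery checks use 200-sample catalogs with
three planted signatures and ten seeded replicates. These sizes were
chosen so the full suite exercises every stage at behaviorally faithful
scale while remaining quick to run.

# Known limitations

* The pooled-null P-values are calibrated against the trimmed background
  fit; if enriched features make up much more than the trim fraction of
  all features, the null re-inflates and recovery degrades.
* Divisive projection clustering explores one direction (by default) per
  node; clusters separated only in directions orthogonal to every
  node's leading components can be missed, and leaf counts can
  occasionally over- or under-shoot by one on unlucky draws — across
  seeded replicates the modal tree matches the planted structure.
* The NMF stability criterion can prefer a smaller $k$ when two planted
  signatures are highly correlated.
* Consequence types are consumed, never predicted; transcript
  enrichment requires transcript annotations on the input mutations.
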