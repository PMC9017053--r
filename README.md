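# genemotif

Subtype discovery for cancer somatic-mutation cohorts from **gene-motif**
features: compound features pairing a mutated gene with the trinucleotide
substitution class (one of the 96 strand-collapsed SBS classes) of the
mutation. Two samples that mutate the *same* gene in *different* sequence
contexts carry different gene-motifs — information that gene-level
recurrence analysis discards and that this package uses to separate
subtypes, characterize them, and link them to mutational processes and
clinical outcome.

The package is aimed at computational cancer-genomics analysts working
with somatic SNV tables (ICGC/MAF-style), a reference FASTA and a gene
annotation (GTF or BED with a coding/lncRNA biotype tag).

## The statistical core

* **Per-gene null** — for gene $g$, $k_g$ = number of distinct samples
  with a mutation in the gene body. One negative binomial
  ($\Pr(X=i) = \binom{i+r-1}{r-1} p^r q^i$, mean $rq/p$) is fitted to the
  pooled counts (top 5% trimmed so enriched genes do not inflate their
  own null) and each gene is scored by $P(X \ge k_g)$; genes with
  $p < 0.01$ are significant.
* **Per-gene-motif null** — within significant genes, the same
  construction with a beta-binomial
  $\Pr(X=i) = \binom{n}{i} B(i+\alpha, n-i+\beta)/B(\alpha,\beta)$ over
  cohort size $n$. Distribution choice is supported by Cullen–Frey
  diagnostics and Cramér–von Mises ranking.
* **Clustering** — recursive model-based clustering of the binarized
  significant gene-motif matrix: each node is re-standardized, projected
  on its leading principal direction(s), fitted with a BIC-selected
  Gaussian mixture, subjected to a meaningful-cluster floor (1% of the
  cohort; smaller children merge back as outliers) and pairwise split
  validation, then recursed. Terminal leaves are the subtypes SC1..SCm.
* **Characterization** — subtype-vs-rest Fisher exact scans (genes,
  lncRNAs, transcripts, gene-motifs), per-subtype motif preferences,
  consequence-type tables, coding-vs-lncRNA load, hypergeometric
  over-representation against GMT gene sets.
* **Signatures** — KL-NMF of the samples × 96 catalog with
  stability-selected signature count and Pearson matching to a
  reference signature matrix.
* **Survival** — Kaplan–Meier curves and the k-group log-rank test per
  subtype.

A seeded synthetic-cohort generator (`cohort_config()` /
`generate_cohort()`) plants a two-level subtype structure with known
truth, so every stage of the pipeline is testable end-to-end without
access to controlled patient data.

## Worked example

```r
library(genemotif)

cohort <- generate_cohort(cohort_config(seed = 42))  # 533 samples
result <- gene_motif_pipeline(cohort$mutations, cohort$reference,
                              cohort$genes,
                              config = clustering_config(seed = 1))

length(result$significant_genes)    # 48 significantly mutated genes
length(result$significant_motifs)   # 272 significant gene-motifs
print(result$tree)
table(result$assignment$subtype)
```

```
recursive clustering of 533 samples -> 7 terminal subtype(s); meaningful-cluster floor = 6
node 1: n = 533  (G = 2, V)
  node 2: n = 450  (G = 3, V)
    node 3: n = 205  [subtype]
    node 4: n = 108  (G = 2, E)
      node 5: n = 64  [subtype]
      node 6: n = 44  [subtype]
    node 7: n = 137  [subtype]
  node 8: n = 83  (G = 4, E)
    node 9: n = 49  [subtype]
    node 10: n = 13  [subtype]
    node 11: n = 21  [subtype]

SC1 SC2 SC3 SC4 SC5 SC6 SC7
205 137  64  44  49  21  13
```

The first clustering level separates two sample groups (450 and 83); the
second level resolves them into 4 + 3 subtypes. Compared against the
generator's planted truth the assignment reaches an adjusted Rand index
of 1.0, and all 270 planted enriched gene-motifs sit in the significant
set (2 background features join them). Downstream:

```r
scan <- subtype_feature_scan(result$feature_matrix, result$assignment)
clin <- merge(cohort$clinical, result$assignment, by = "sample_id")
logrank_test(clin$survival_time_days, clin$event, clin$subtype)
#> log-rank test: chisq = 62.97 on 6 df, p = 1.122e-11  [p < 1e-4]
```

A thin CLI covering simulate / annotate / pipeline / signatures /
survival ships in `inst/cli/genemotif`.

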