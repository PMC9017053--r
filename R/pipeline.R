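#' Run the full gene-motif subtyping pipeline
#'
#' Convenience wrapper chaining the pipeline stages: annotate mutations
#' against the gene models and reference, count mutated samples per gene,
#' select significantly mutated genes under the pooled negative-binomial
#' background, build the gene-motif matrix restricted to those genes,
#' select significant gene-motifs under the pooled beta-binomial
#' background, and cluster samples recursively on the binarized significant
#' gene-motif matrix.
#'
#' @param mutations MAF-lite data.frame (see [read_mutations()]).
#' @param reference [Biostrings::DNAStringSet].
#' @param genes Gene model data.frame.
#' @param threshold Significance threshold for both levels (default 0.01).
#' @param gene_biotype Biotypes eligible for the significant-gene set
#'   (default `"coding"`, matching the convention that gene-motif features
#'   are built within significantly mutated protein-coding genes).
#' @param config A [clustering_config()].
#' @return List: `annotated`, `gene_counts`, `gene_results`,
#'   `significant_genes`, `gene_motif` (matrix object), `motif_results`,
#'   `significant_motifs`, `feature_matrix` (binary, significant features
#'   only), `tree`, `assignment`.
#' @export
gene_motif_pipeline <- function(mutations, reference, genes,
                                threshold = 0.01, gene_biotype = "coding",
                                config = clustering_config()) {
  annotated <- annotate_genes(mutations, genes, reference)
  gene_counts <- build_gene_counts(annotated, genes)
  gene_results <- gene_significance(gene_counts, threshold = threshold,
                                    biotype = gene_biotype)
  significant_genes <- select_significant(gene_results, threshold)
  if (length(significant_genes) == 0) {
    stop("no significantly mutated genes at threshold ", threshold)
  }
  samples <- sort(unique(mutations$sample_id))
  gm <- build_gene_motif_matrix(annotated, significant_genes,
                                samples = samples)
  motif_results <- gene_motif_significance(gm$count_table,
                                           threshold = threshold)
  significant_motifs <- select_significant(motif_results, threshold)
  if (length(significant_motifs) == 0) {
    stop("no significant gene-motifs at threshold ", threshold)
  }
  feature_matrix <- as.matrix(gm$binary[, significant_motifs,
                                        drop = FALSE])
  tree <- recursive_cluster(feature_matrix, config)
  assignment <- assign_subtypes(tree)
  list(annotated = annotated, gene_counts = gene_counts,
       gene_results = gene_results,
       significant_genes = significant_genes,
       gene_motif = gm, motif_results = motif_results,
       significant_motifs = significant_motifs,
       feature_matrix = feature_matrix, tree = tree,
       assignment = assignment)
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected agreement between two labelings of the same
#' samples; 1 means identical partitions, 0 the chance level. Used to
#' compare recovered subtypes with planted truth.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
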