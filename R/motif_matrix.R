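#' Per-gene mutated-sample counts
#'
#' The gene-level statistic of the pipeline is `k`: the number of distinct
#' samples carrying at least one mutation in the gene body. Genes with no
#' mutation are retained with `k = 0` (they inform the low tail of the
#' pooled background fit).
#'
#' @param annotated Data.frame from [annotate_genes()] (one row per
#'   mutation-gene pair; intergenic rows are ignored).
#' @param genes Gene model data.frame; all its genes appear in the output.
#' @return A data.frame (gene_id, biotype, k, n_mutations) and, as attribute
#'   `"sample_gene"`, a data.frame of per-(sample, gene) raw mutation counts.
#' @export
build_gene_counts <- function(annotated, genes) {
  ing <- annotated[!is.na(annotated$gene_id), , drop = FALSE]
  key <- paste(ing$sample_id, ing$gene_id, sep = "\r")
  sg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(as.character(sg$key), "\r", fixed = TRUE)
  sample_gene <- data.frame(
    sample_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    n_mutations = sg$Freq,
    stringsAsFactors = FALSE)
  k <- table(sample_gene$gene_id)
  nm <- table(ing$gene_id)
  kv <- as.integer(k[match(genes$gene_id, names(k))])
  nv <- as.integer(nm[match(genes$gene_id, names(nm))])
  kv[is.na(kv)] <- 0L
  nv[is.na(nv)] <- 0L
  out <- data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
                    k = kv, n_mutations = nv, stringsAsFactors = FALSE)
  attr(out, "sample_gene") <- sample_gene
  out
}

#' Build the samples x gene-motif matrix
#'
#' Aggregates annotated mutations into the clustering feature space: rows
#' are samples, columns are (gene, motif-class) pairs named
#' `"<gene_id>|<class>"`, cells count mutations of that class in that gene
#' for that sample. Columns are restricted to `gene_subset` (typically the
#' significantly mutated genes) and only columns with at least one mutation
#' are materialized. A binarized view and a per-column distinct-sample count
#' table (the `k` of the beta-binomial model, with cohort size `n`) are
#' returned alongside.
#'
#' @param annotated Data.frame from [annotate_genes()]; rows with `NA` motif
#'   (context unavailable) or `NA` gene are ignored.
#' @param gene_subset Character vector of gene ids to keep (non-empty).
#' @param samples Optional character vector fixing the row universe (cohort);
#'   defaults to all samples observed in `annotated`.
#' @return A list of class `"gene_motif_matrix"` with elements `counts` and
#'   `binary` (sparse [Matrix::sparseMatrix] objects, samples x features) and
#'   `count_table` (data.frame gene_id, motif, feature, k, n).
#' @export
build_gene_motif_matrix <- function(annotated, gene_subset, samples = NULL) {
  if (length(gene_subset) == 0) {
    stop("gene_subset is empty: no features to build")
  }
  if (is.null(samples)) samples <- sort(unique(annotated$sample_id))
  use <- !is.na(annotated$gene_id) & !is.na(annotated$motif) &
    annotated$gene_id %in% gene_subset
  ann <- annotated[use, , drop = FALSE]
  feature <- paste(ann$gene_id, ann$motif, sep = "|")
  # full gene_subset x 96 grid: zero-count features are retained (they
  # anchor the low tail of the pooled beta-binomial background fit)
  feat_levels <- paste(rep(sort(unique(gene_subset)), each = 96),
                       motif_classes(), sep = "|")
  if (nrow(ann) == 0) {
    stop("no context-available mutations fall in gene_subset")
  }
  i <- match(ann$sample_id, samples)
  if (anyNA(i)) stop("annotated mutations contain samples outside 'samples'")
  j <- match(feature, feat_levels)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(samples),
                                          length(feat_levels)),
                                 dimnames = list(samples, feat_levels))
  binary <- counts
  binary@x <- rep(1, length(binary@x))
  binary <- Matrix::drop0(binary)
  k <- Matrix::colSums(binary)
  parts <- strsplit(feat_levels, "|", fixed = TRUE)
  count_table <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    motif = vapply(parts, `[`, "", 2L),
    feature = feat_levels,
    k = as.integer(k),
    n = length(samples),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, binary = binary,
                 count_table = count_table),
            class = "gene_motif_matrix")
}

#' @export
print.gene_motif_matrix <- function(x, ...) {
  cat("gene-motif matrix:", nrow(x$counts), "samples x",
      ncol(x$counts), "gene-motif features\n")
  cat("  total mutation-feature entries:", sum(x$counts), "\n")
  invisible(x)
}

#' Write a gene-motif matrix as MTX + label files and TSV count table
#' @param x A `"gene_motif_matrix"`.
#' @param prefix Output path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.rows.txt`, `<prefix>.cols.txt`, `<prefix>.counts.tsv`.
#' @export
write_gene_motif_matrix <- function(x, prefix) {
  Matrix::writeMM(x$counts, paste0(prefix, ".mtx"))
  writeLines(rownames(x$counts), paste0(prefix, ".rows.txt"))
  writeLines(colnames(x$counts), paste0(prefix, ".cols.txt"))
  utils::write.table(x$count_table, paste0(prefix, ".counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
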