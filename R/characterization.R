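#' Fisher's exact test on a 2x2 subtype-vs-rest table
#'
#' The table rows are (mutated, not mutated) and the columns (subtype,
#' rest): `a` subtype samples mutated, `b` subtype samples not mutated, `c`
#' rest mutated, `d` rest not mutated. The two-sided exact P-value follows
#' the point-probability rule (sum of hypergeometric table probabilities
#' not exceeding the observed one), as computed by [stats::fisher.test];
#' the unit tests verify it against a direct enumeration of all tables with
#' the observed margins. The reported odds ratio is the sample odds ratio
#' `(a d)/(b c)` (not the conditional MLE), with `Inf` when only `b c` is
#' zero and `NA` when the ratio is 0/0 or a margin is empty.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return List: `odds_ratio`, `p_value`, `table` (2x2 matrix).
#' @export
#' @examples
#' fisher_exact(42, 2, 144, 345)  # subtype-specific gene example
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be nonnegative")
  tab <- matrix(c(a, b, c, d), nrow = 2,
                dimnames = list(c("mutated", "not_mutated"),
                                c("subtype", "rest")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  }
  p <- stats::fisher.test(tab)$p.value
  or <- if (b == 0 && c == 0) NA_real_
        else if (a == 0 && d == 0) NA_real_
        else (a * d) / (b * c)   # Inf when b*c == 0 and a*d > 0
  list(odds_ratio = or, p_value = min(p, 1), table = tab)
}

#' Subtype-vs-rest Fisher scan over a binary feature matrix
#'
#' For every (feature, subtype) pair, tests whether the feature is mutated
#' more often inside the subtype than in the rest of the cohort (Fisher's
#' exact, two-sided). Benjamini-Hochberg q-values are computed within each
#' subtype's scan. Features mutated in a subtype and in no other sample are
#' flagged `unique_to_subtype`.
#'
#' @param matrix Binary matrix, samples x features (genes, lncRNAs,
#'   transcripts or gene-motifs), rows named by sample id.
#' @param assignment Data.frame (sample_id, subtype).
#' @return Data.frame: feature_id, subtype, a, b, c, d, odds_ratio,
#'   p_value, q_value, unique_to_subtype.
#' @export
subtype_feature_scan <- function(matrix, assignment) {
  m <- as.matrix(matrix) > 0
  idx <- match(rownames(m), assignment$sample_id)
  if (anyNA(idx)) stop("matrix rows missing from subtype assignment")
  subtype <- assignment$subtype[idx]
  labs <- sort(unique(subtype))
  tot_mut <- colSums(m)
  out <- list()
  for (s in labs) {
    ins <- subtype == s
    a <- colSums(m[ins, , drop = FALSE])
    b <- sum(ins) - a
    c_ <- tot_mut - a
    d <- sum(!ins) - c_
    p <- vapply(seq_len(ncol(m)), function(j) {
      fisher_exact(a[j], b[j], c_[j], d[j])$p_value
    }, numeric(1))
    or <- ifelse(b * c_ > 0, (a * d) / (b * c_),
                 ifelse(a * d > 0, Inf, NA_real_))
    out[[s]] <- data.frame(
      feature_id = colnames(m), subtype = s,
      a = as.integer(a), b = as.integer(b),
      c = as.integer(c_), d = as.integer(d),
      odds_ratio = or, p_value = p,
      q_value = stats::p.adjust(p, "BH"),
      unique_to_subtype = a > 0 & c_ == 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subtype motif preference of a gene
#'
#' For one gene, computes per subtype the fraction of subtype samples
#' mutated in each of the 96 substitution classes within that gene; the
#' dominant motif(s) (argmax, ties reported jointly) summarize the
#' subtype's sequence-context preference.
#'
#' @param annotated Data.frame from [annotate_genes()].
#' @param assignment Data.frame (sample_id, subtype).
#' @param gene Gene id.
#' @return List keyed by subtype, each with `fractions` (named 96-vector)
#'   and `dominant` (character vector of class names; empty when the gene
#'   is unmutated in the subtype).
#' @export
motif_preference <- function(annotated, assignment, gene) {
  ann <- annotated[!is.na(annotated$gene_id) & annotated$gene_id == gene &
                     !is.na(annotated$motif), , drop = FALSE]
  classes <- motif_classes()
  labs <- sort(unique(assignment$subtype))
  out <- list()
  for (s in labs) {
    members <- assignment$sample_id[assignment$subtype == s]
    sub <- ann[ann$sample_id %in% members, , drop = FALSE]
    frac <- vapply(classes, function(cl) {
      length(unique(sub$sample_id[sub$motif == cl])) / length(members)
    }, numeric(1))
    dominant <- if (all(frac == 0)) character(0)
                else classes[frac == max(frac)]
    out[[s]] <- list(fractions = frac, dominant = dominant)
  }
  out
}

#' Consequence-type relative frequencies per subtype
#'
#' The controlled vocabulary of variant consequence categories used for
#' reporting (mutations with other labels are pooled into `"other"` with a
#' warning). Percentages are of each subtype's total mutations, so each
#' subtype column sums to 100.
#'
#' @param mutations Data.frame with `sample_id` and `consequence_type`.
#' @param assignment Data.frame (sample_id, subtype).
#' @return Matrix consequence-types x subtypes of percentages.
#' @export
consequence_table <- function(mutations, assignment) {
  if (!"consequence_type" %in% names(mutations) ||
      all(is.na(mutations$consequence_type))) {
    warning("no consequence_type annotations: skipping consequence table")
    return(NULL)
  }
  vocab <- consequence_vocabulary()
  ct <- mutations$consequence_type
  unknown <- !is.na(ct) & !ct %in% vocab
  if (any(unknown)) {
    warning(sum(unknown), " mutation(s) with consequence labels outside ",
            "the controlled vocabulary, pooled as 'other'")
    ct[unknown] <- "other"
  }
  keep <- !is.na(ct)
  idx <- match(mutations$sample_id[keep], assignment$sample_id)
  subtype <- assignment$subtype[idx]
  lv <- c(vocab, if (any(unknown)) "other")
  tab <- table(factor(ct[keep], levels = lv), subtype)
  pct <- sweep(tab, 2, colSums(tab), "/") * 100
  as.matrix(pct)
}

#' The consequence-type controlled vocabulary (19 categories)
#' @return Character vector.
#' @export
consequence_vocabulary <- function() {
  c("3_prime_UTR_variant",
    "5_prime_UTR_premature_start_codon_gain_variant",
    "5_prime_UTR_variant", "downstream_gene_variant", "exon_variant",
    "initiator_codon_variant", "intergenic_region", "intragenic_variant",
    "intron_variant", "missense_variant", "splice_acceptor_variant",
    "splice_donor_variant", "splice_region_variant", "start_lost",
    "stop_gained", "stop_lost", "stop_retained_variant",
    "synonymous_variant", "upstream_gene_variant")
}

#' Per-subtype mutational load in coding vs lncRNA genes
#'
#' Mean per-sample counts of gene-linked mutations, split by gene biotype,
#' for each subtype. Subtypes whose overall mean load exceeds the cohort
#' mean by more than two cohort standard deviations (of per-sample totals)
#' are flagged hyper-mutated.
#'
#' @param annotated Data.frame from [annotate_genes()].
#' @param assignment Data.frame (sample_id, subtype).
#' @return List: `per_subtype` (data.frame subtype, coding_mean,
#'   lncRNA_mean, total_mean, hyper_mutated), `per_sample` (data.frame).
#' @export
mutational_load <- function(annotated, assignment) {
  ing <- annotated[!is.na(annotated$gene_id), , drop = FALSE]
  # count each mutation once per (sample, mutation, biotype)
  key <- paste(ing$sample_id, ing$chrom, ing$pos, ing$alt, ing$biotype,
               sep = "\r")
  ing <- ing[!duplicated(key), , drop = FALSE]
  samples <- assignment$sample_id
  per_sample <- data.frame(
    sample_id = samples,
    subtype = assignment$subtype,
    coding = as.integer(table(factor(
      ing$sample_id[ing$biotype == "coding"], levels = samples))),
    lncRNA = as.integer(table(factor(
      ing$sample_id[ing$biotype == "lncRNA"], levels = samples))),
    stringsAsFactors = FALSE)
  per_sample$total <- per_sample$coding + per_sample$lncRNA
  mu <- mean(per_sample$total)
  sdv <- stats::sd(per_sample$total)
  labs <- sort(unique(assignment$subtype))
  per_subtype <- do.call(rbind, lapply(labs, function(s) {
    sub <- per_sample[per_sample$subtype == s, , drop = FALSE]
    data.frame(subtype = s,
               coding_mean = mean(sub$coding),
               lncRNA_mean = mean(sub$lncRNA),
               total_mean = mean(sub$total),
               hyper_mutated = mean(sub$total) > mu + 2 * sdv,
               stringsAsFactors = FALSE)
  }))
  list(per_subtype = per_subtype, per_sample = per_sample)
}

#' Transcript-level subtype enrichment
#'
#' Per (transcript, subtype) Fisher's exact test of mutated-sample counts
#' versus the rest of the cohort, plus the fraction of subtype samples
#' mutated per transcript. Mutations must carry a `transcript_id`.
#'
#' @param mutations Data.frame with `sample_id` and `transcript_id`.
#' @param assignment Data.frame (sample_id, subtype).
#' @return List: `fisher` (data.frame as [subtype_feature_scan()]),
#'   `fractions` (transcripts x subtypes matrix), or `NULL` with a warning
#'   when no transcript information is present.
#' @export
transcript_enrichment <- function(mutations, assignment) {
  if (!"transcript_id" %in% names(mutations) ||
      all(is.na(mutations$transcript_id) | mutations$transcript_id == "")) {
    warning("no transcript_id annotations: transcript enrichment skipped")
    return(NULL)
  }
  mt <- mutations[!is.na(mutations$transcript_id) &
                    mutations$transcript_id != "", , drop = FALSE]
  samples <- assignment$sample_id
  txs <- sort(unique(mt$transcript_id))
  m <- matrix(0L, length(samples), length(txs),
              dimnames = list(samples, txs))
  key <- unique(data.frame(s = mt$sample_id, t = mt$transcript_id))
  m[cbind(match(key$s, samples), match(key$t, txs))] <- 1L
  fisher <- subtype_feature_scan(m, assignment)
  labs <- sort(unique(assignment$subtype))
  fractions <- vapply(labs, function(s) {
    members <- assignment$sample_id[assignment$subtype == s]
    colSums(m[members, , drop = FALSE]) / length(members)
  }, numeric(length(txs)))
  list(fisher = fisher, fractions = fractions)
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, then member genes, per line,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of `gene_list` relative to
#' `universe` with the upper-tail hypergeometric probability
#' `P(overlap >= observed)`, followed by Benjamini-Hochberg correction
#' across the sets tested. A generic stand-in for web-based enrichment
#' tools against any user-supplied GMT collection.
#'
#' @param gene_list Character vector of genes of interest (must be a subset
#'   of `universe`; genes outside are dropped with a warning).
#' @param gene_sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: the annotation universe.
#' @param min_set_size Sets with fewer in-universe members are skipped
#'   (default 5).
#' @param fdr Significance threshold on q (default 0.05).
#' @return Data.frame: set, set_size, overlap, p_value, q_value,
#'   significant; ordered by p.
#' @export
ora_hypergeometric <- function(gene_list, gene_sets, universe,
                               min_set_size = 5, fdr = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0) {
    warning(length(outside), " gene(s) of interest outside the universe, ",
            "dropped")
  }
  gl <- intersect(unique(gene_list), universe)
  rows <- list()
  for (nm in names(gene_sets)) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    if (length(set) < min_set_size) next
    ov <- length(intersect(gl, set))
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(gl), lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, set_size = length(set),
                             overlap = ov, p_value = p,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop("no gene set overlaps the universe at min_set_size = ",
         min_set_size)
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < fdr
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
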