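#' Read somatic point mutations from a MAF-lite TSV
#'
#' Expects a tab-separated file with a header and at least the columns
#' `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`. Optional columns
#' `consequence_type` and `transcript_id` are carried through when present.
#' Rows violating the single-nucleotide-variant contract (non-ACGT alleles,
#' `ref == alt`, non-positive position) are rejected with line-numbered
#' messages; multi-allelic `alt` values (comma-separated) are split into one
#' record per alternate allele.
#'
#' @param path Path to the TSV file.
#' @param quiet Suppress per-row rejection messages.
#' @return A data.frame of mutation records with attribute `"n_rejected"`.
#' @export
read_mutations <- function(path, quiet = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("mutation file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    out <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1

  # split multi-allelic alts before validation
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  reps <- lengths(alts)
  df <- df[rep(seq_len(nrow(df)), reps), , drop = FALSE]
  df$alt <- unlist(alts)

  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  pos <- suppressWarnings(as.integer(df$pos))
  ok_base <- df$ref %in% names(COMPLEMENT) & df$alt %in% names(COMPLEMENT)
  ok <- ok_base & !is.na(pos) & pos >= 1L & df$ref != df$alt &
    nzchar(df$sample_id) & nzchar(df$chrom)
  if (any(!ok) && !quiet) {
    bad <- df[!ok, , drop = FALSE]
    for (i in seq_len(min(nrow(bad), 20L))) {
      message(sprintf("read_mutations: rejected line %d (%s %s %s>%s)",
                      bad$.line[i], bad$chrom[i], bad$pos[i],
                      bad$ref[i], bad$alt[i]))
    }
    if (nrow(bad) > 20L) message("... and ", nrow(bad) - 20L, " more")
  }
  n_rejected <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  out <- data.frame(sample_id = df$sample_id, chrom = df$chrom,
                    pos = pos[ok], ref = df$ref, alt = df$alt,
                    stringsAsFactors = FALSE)
  for (opt in c("consequence_type", "transcript_id")) {
    if (opt %in% names(df)) out[[opt]] <- df[[opt]]
  }
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write mutations to a MAF-lite TSV
#' @param mutations Data.frame as returned by [read_mutations()].
#' @param path Output path.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Read gene models from GTF or BED
#'
#' GTF is read natively (1-based inclusive); BED intervals (0-based
#' half-open) are converted on read, which `rtracklayer` does when importing.
#' Gene biotype is taken from the `gene_biotype` (or `gene_type`) attribute
#' for GTF and from the BED `name` column suffix `"|coding"` / `"|lncRNA"`;
#' records without a recognizable biotype default to `"coding"` with a
#' warning.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed"`; guessed from the file extension by
#'   default.
#' @return A list with elements `genes` (data.frame: gene_id, name, biotype,
#'   chrom, start, end, strand) and `transcripts` (data.frame: transcript_id,
#'   gene_id, chrom, start, end, strand; empty for BED input).
#' @export
read_genes <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gtf"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    parts <- strsplit(nm, "|", fixed = TRUE)
    biotype <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
    if (any(!biotype %in% c("coding", "lncRNA"))) {
      warning("BED records without a coding/lncRNA biotype tag; ",
              "defaulting to 'coding'")
      biotype[!biotype %in% c("coding", "lncRNA")] <- "coding"
    }
    genes <- data.frame(
      gene_id = vapply(parts, `[`, "", 1L),
      name = vapply(parts, `[`, "", 1L),
      biotype = biotype,
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
      stringsAsFactors = FALSE)
    return(list(genes = genes,
                transcripts = data.frame(transcript_id = character(),
                                         gene_id = character(),
                                         chrom = character(),
                                         start = integer(), end = integer(),
                                         strand = character())))
  }
  gr <- rtracklayer::import(path, format = "GTF")
  meta <- S4Vectors::mcols(gr)
  typ <- as.character(meta$type)
  bio <- if (!is.null(meta$gene_biotype)) as.character(meta$gene_biotype)
         else if (!is.null(meta$gene_type)) as.character(meta$gene_type)
         else rep(NA_character_, length(gr))
  is_gene <- typ == "gene"
  if (!any(is_gene)) stop("no 'gene' features found in GTF: ", path)
  bio[is.na(bio)] <- "coding"
  bio[!bio %in% c("coding", "lncRNA")] <- "coding"
  gname <- if (!is.null(meta$gene_name)) as.character(meta$gene_name)
           else as.character(meta$gene_id)
  genes <- data.frame(
    gene_id = as.character(meta$gene_id)[is_gene],
    name = gname[is_gene],
    biotype = bio[is_gene],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[is_gene],
    start = BiocGenerics::start(gr)[is_gene],
    end = BiocGenerics::end(gr)[is_gene],
    strand = ifelse(as.character(BiocGenerics::strand(gr))[is_gene] == "-",
                    "-", "+"),
    stringsAsFactors = FALSE)
  is_tx <- typ == "transcript"
  transcripts <- data.frame(
    transcript_id = as.character(meta$transcript_id)[is_tx],
    gene_id = as.character(meta$gene_id)[is_tx],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[is_tx],
    start = BiocGenerics::start(gr)[is_tx],
    end = BiocGenerics::end(gr)[is_tx],
    strand = ifelse(as.character(BiocGenerics::strand(gr))[is_tx] == "-",
                    "-", "+"),
    stringsAsFactors = FALSE)
  list(genes = genes, transcripts = transcripts)
}

#' Trinucleotide context of a genomic position
#'
#' Returns the reference bases at `pos - 1`, `pos`, `pos + 1` (uppercased,
#' +-strand). Positions at a chromosome edge have no complete context and
#' raise an error; such mutations are excluded from motif analyses but still
#' count in gene-level analyses.
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param pos 1-based position (may be a vector).
#' @return Character vector of 3-mers.
#' @export
trinucleotide_context <- function(reference, chrom, pos) {
  if (!chrom %in% names(reference)) {
    stop("chromosome not in reference: ", chrom)
  }
  len <- length(reference[[chrom]])
  if (any(pos < 2L | pos > len - 1L)) {
    stop("position(s) at chromosome edge: no trinucleotide context ",
         "available (chrom ", chrom, ", length ", len, ")")
  }
  toupper(as.character(Biostrings::extractAt(
    reference[[chrom]], IRanges::IRanges(pos - 1L, pos + 1L))))
}

#' Annotate mutations with overlapping genes and motif classes
#'
#' Each mutation is assigned all genes whose body (TSS to TES, 1-based
#' inclusive) covers its position — a mutation inside k overlapping genes
#' yields k annotation rows (set `multi_gene = "longest"` to keep only the
#' longest covering gene). Mutations outside every gene are retained with
#' `gene_id = NA` (intergenic). The trinucleotide substitution class is
#' computed from the reference; mutations at chromosome edges or whose
#' reference allele disagrees with the reference sequence get `motif = NA`
#' and are excluded from motif-level analyses downstream.
#'
#' @param mutations Data.frame from [read_mutations()].
#' @param genes Data.frame of gene models (`$genes` from [read_genes()]).
#' @param reference [Biostrings::DNAStringSet]; if `NULL`, motif classes are
#'   not computed.
#' @param multi_gene `"all"` (default) or `"longest"`.
#' @return A data.frame with one row per (mutation, gene) pair, columns of
#'   `mutations` plus `gene_id`, `biotype`, `context` and `motif`.
#' @export
annotate_genes <- function(mutations, genes, reference = NULL,
                           multi_gene = c("all", "longest")) {
  multi_gene <- match.arg(multi_gene)
  mut_chr <- unique(mutations$chrom)
  gene_chr <- unique(genes$chrom)
  unmatched <- setdiff(mut_chr, gene_chr)
  if (!is.null(reference)) {
    bad_ref <- setdiff(mut_chr, names(reference))
    if (length(bad_ref) > 0) {
      stop("chromosome name(s) in mutations absent from reference: ",
           paste(bad_ref, collapse = ", "))
    }
  } else if (length(unmatched) == length(mut_chr) && length(mut_chr) > 0) {
    stop("no chromosome names shared between mutations and genes; ",
         "unmatched: ", paste(unmatched, collapse = ", "))
  }

  mut_gr <- GenomicRanges::GRanges(mutations$chrom,
                                   IRanges::IRanges(mutations$pos,
                                                    mutations$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mut_gr, gene_gr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (multi_gene == "longest" && length(qh) > 0) {
    glen <- genes$end[sh] - genes$start[sh]
    ord <- order(qh, -glen)
    keep <- !duplicated(qh[ord])
    qh <- qh[ord][keep]; sh <- sh[ord][keep]
  }
  no_gene <- setdiff(seq_len(nrow(mutations)), unique(qh))
  idx <- c(qh, no_gene)
  gidx <- c(sh, rep(NA_integer_, length(no_gene)))
  ord <- order(idx)
  idx <- idx[ord]; gidx <- gidx[ord]

  out <- mutations[idx, , drop = FALSE]
  out$gene_id <- ifelse(is.na(gidx), NA_character_, genes$gene_id[gidx])
  out$biotype <- ifelse(is.na(gidx), NA_character_, genes$biotype[gidx])

  out$context <- NA_character_
  out$motif <- NA_character_
  if (!is.null(reference)) {
    for (chr in unique(out$chrom)) {
      sel <- which(out$chrom == chr)
      len <- length(reference[[chr]])
      inner <- sel[out$pos[sel] >= 2L & out$pos[sel] <= len - 1L]
      if (length(inner) == 0) next
      ctx <- trinucleotide_context(reference, chr, out$pos[inner])
      match_ref <- substr(ctx, 2L, 2L) == out$ref[inner]
      out$context[inner[match_ref]] <- ctx[match_ref]
      if (any(!match_ref)) {
        warning(sum(!match_ref), " mutation(s) on ", chr,
                " whose ref allele disagrees with the reference sequence; ",
                "motif left NA")
      }
      ok <- inner[match_ref]
      if (length(ok) > 0) {
        out$motif[ok] <- classify_motif(out$context[ok], out$ref[ok],
                                        out$alt[ok])
      }
    }
  }
  rownames(out) <- NULL
  out
}
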