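#' The 96 strand-collapsed trinucleotide substitution classes
#'
#' Somatic single-base substitutions are conventionally grouped into 96
#' classes: the mutated base is reported on the pyrimidine strand (reference
#' base C or T, giving six substitutions C>A, C>G, C>T, T>A, T>C, T>G), and
#' each substitution is further resolved by its immediate 5' and 3' flanking
#' bases. Classes are written `"5'[ref>alt]3'"`, e.g. `"A[C>T]G"`.
#'
#' The canonical ordering (used for every matrix column order in this
#' package) sorts first by substitution (C>A, C>G, C>T, T>A, T>C, T>G), then
#' by 5' base (A, C, G, T), then by 3' base (A, C, G, T). This matches the
#' ordering used by the COSMIC SBS-96 catalogs, so externally supplied
#' reference signature matrices in that order line up without reshuffling.
#'
#' @return Character vector of the 96 class names in canonical order.
#' @export
#' @examples
#' head(motif_classes())
motif_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = bases, p5 = bases, sub = subs,
                      stringsAsFactors = FALSE)
  # expand.grid varies its first factor fastest; we want sub > 5' > 3'
  paste0(grid$p5, "[", grid$sub, "]", grid$p3)
}

#' Index of a motif class in the canonical ordering
#'
#' @param class Character vector of class names as produced by
#'   [classify_motif()] or [motif_classes()].
#' @return Integer vector of positions in `1:96`; unknown names are an error.
#' @export
motif_index <- function(class) {
  idx <- match(class, motif_classes())
  if (anyNA(idx)) {
    stop("unknown motif class: ",
         paste(unique(class[is.na(idx)]), collapse = ", "))
  }
  idx
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA string
#'
#' Minimal uppercase ACGT reverse complement used by the motif classifier.
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' Classify a substitution into one of the 96 trinucleotide classes
#'
#' Takes the trinucleotide context on the reference (+) strand together with
#' the reference and alternate alleles and returns the strand-collapsed class
#' name. When the reference base is a purine (A or G) the context and both
#' alleles are reverse-complemented before naming, so every class has a
#' pyrimidine reference base. The mapping is strand-symmetric: a substitution
#' and its reverse complement land in the same class, and each of the 96
#' classes is reachable from exactly two raw (context, ref, alt) triples.
#'
#' @param context Character vector of 3-mers over ACGT (the +-strand
#'   reference bases at positions pos-1, pos, pos+1).
#' @param ref,alt Single-base reference and alternate alleles; the middle
#'   base of `context` must equal `ref`.
#' @return Character vector of class names, e.g. `"A[C>T]G"`.
#' @export
#' @examples
#' classify_motif("ACG", "C", "T")   # "A[C>T]G"
#' classify_motif("TGC", "G", "A")   # collapses to "G[C>T]A"
classify_motif <- function(context, ref, alt) {
  context <- toupper(context)
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- max(length(context), length(ref), length(alt))
  context <- rep_len(context, n); ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(nchar(context) != 3L)) stop("context must be a 3-mer")
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("ref/alt must be single bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  mid <- substr(context, 2L, 2L)
  if (any(mid != ref)) {
    stop("context middle base does not match ref at ",
         sum(mid != ref), " position(s)")
  }
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    context[pur] <- revcomp(context[pur])
    ref[pur] <- unname(COMPLEMENT[ref[pur]])
    alt[pur] <- unname(COMPLEMENT[alt[pur]])
  }
  paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context, 3L, 3L))
}
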