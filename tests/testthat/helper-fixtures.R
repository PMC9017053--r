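# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# A moderate planted cohort, large enough for the significance and
# clustering stages to behave as at study scale but quick to generate.
small_cohort_config <- function(seed = 7L) {
  cohort_config(
    n_samples = 180,
    subtype_sizes = c(30, 60, 40, 20, 15, 15),
    superclusters = list(1:3, 4:6),
    n_genes = 150, n_lncrna = 100,
    n_driver_genes = 25,
    enriched_motifs_per_subtype = 12,
    supercluster_motifs = 15,
    hyper_subtype = 4,
    n_chroms = 2, chrom_len = 250000,
    seed = seed)
}

get_small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(small_cohort_config())
  }
  .fixture_env$small
}

get_small_annotated <- function() {
  if (is.null(.fixture_env$small_ann)) {
    coh <- get_small_cohort()
    .fixture_env$small_ann <- annotate_genes(coh$mutations, coh$genes,
                                             coh$reference)
  }
  .fixture_env$small_ann
}

# The default study-scale cohort shared by the end-to-end tests.
get_default_cohort <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_cohort(cohort_config())
  }
  .fixture_env$default
}

get_default_pipeline <- function() {
  if (is.null(.fixture_env$default_pipeline)) {
    coh <- get_default_cohort()
    .fixture_env$default_pipeline <- gene_motif_pipeline(
      coh$mutations, coh$reference, coh$genes,
      config = clustering_config(seed = 1))
  }
  .fixture_env$default_pipeline
}

# A tiny handmade reference with two genes for annotation edge cases.
tiny_reference <- function() {
  ref <- Biostrings::DNAStringSet(c(
    chrA = "ACGTACGTACGTACGTACGTACGTACGTACGT",
    chrB = "TTTTCCCCGGGGAAAATTTTCCCCGGGGAAAA"))
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3"),
    name = c("G1", "G2", "G3"),
    biotype = c("coding", "lncRNA", "coding"),
    chrom = c("chrA", "chrA", "chrB"),
    start = c(5L, 10L, 3L),
    end = c(20L, 24L, 30L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  list(reference = ref, genes = genes)
}

# Independent product-limit computation used as the KM oracle.
manual_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    n_i <- sum(time >= times[i])
    d_i <- sum(time == times[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}
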