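test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_samples = 10, subtype_sizes = c(5, 4)),
               "must equal")
  expect_error(cohort_config(n_samples = 9, subtype_sizes = c(5, 4),
                             superclusters = list(1)), "partition")
  expect_error(cohort_config(enrichment_prob = 1.5), "probabilities")
  expect_error(cohort_config(background_nb_mean = -1), "positive")
  cfg <- cohort_config()
  expect_equal(sum(cfg$subtype_sizes), 533)
  expect_equal(cfg$subtype_sizes, c(44, 137, 64, 205, 13, 49, 21))
})

test_that("reference generation is deterministic with disjoint gene bodies", {
  r1 <- generate_reference(2, 10000, seed = 3, n_genes = 12, n_lncrna = 8,
                           gene_length = c(300, 500), margin = 100)
  r2 <- generate_reference(2, 10000, seed = 3, n_genes = 12, n_lncrna = 8,
                           gene_length = c(300, 500), margin = 100)
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  expect_identical(r1$genes, r2$genes)
  # all gene intervals disjoint and in bounds, per chromosome
  for (chr in unique(r1$genes$chrom)) {
    g <- r1$genes[r1$genes$chrom == chr, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start >= 1 & g$end <= 10000))
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # transcripts nest inside their gene
  tx <- merge(r1$transcripts, r1$genes, by = "gene_id")
  expect_true(all(tx$start.x >= tx$start.y & tx$end.x <= tx$end.y))

  # minimal chromosome: a single 3-mer, no genes requested
  tiny <- generate_reference(1, 3, seed = 1, n_genes = 0, n_lncrna = 0)
  expect_equal(length(tiny$reference[[1]]), 3)
  expect_equal(nrow(tiny$genes), 0)
  expect_error(generate_reference(1, 500, seed = 1, n_genes = 50,
                                  n_lncrna = 0),
               "too small")
})

test_that("cohort generation is deterministic and allele-consistent", {
  cfg <- small_cohort_config(seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth$enriched, c2$truth$enriched)

  coh <- get_small_cohort()
  seqs <- as.character(coh$reference)
  m <- coh$mutations
  ref_base <- substr(seqs[m$chrom],
                     m$pos, m$pos)
  # exhaustive allele consistency
  expect_true(all(mapply(function(chr, pos, ref) {
    substr(seqs[[chr]], pos, pos) == ref
  }, m$chrom, m$pos, m$ref)))
  expect_true(all(m$ref != m$alt))
})

test_that("planted gene-motifs are realizable and planted where promised", {
  coh <- get_small_cohort()
  ann <- get_small_annotated()
  enr <- rbind(coh$truth$enriched[, c("gene_id", "motif", "feature")],
               coh$truth$supercluster_enriched[, c("gene_id", "motif",
                                                   "feature")])
  observed <- paste(ann$gene_id, ann$motif, sep = "|")
  # every planted feature is actually observed as mutations of that class
  expect_true(all(enr$feature %in% observed))
})

test_that("degenerate probabilities give a block-diagonal planted matrix", {
  cfg <- cohort_config(
    n_samples = 60, subtype_sizes = c(20, 20, 20),
    superclusters = list(1:2, 3), n_genes = 60, n_lncrna = 20,
    n_driver_genes = 12, enriched_motifs_per_subtype = 6,
    supercluster_motifs = 0,
    enrichment_prob = 1.0, background_motif_prob = 0.0,
    background_nb_mean = 0.5, driver_background_mean = 0.5,
    hyper_subtype = NA, intergenic_rate = 2,
    n_chroms = 1, chrom_len = 200000, seed = 12)
  coh <- generate_cohort(cfg)
  ann <- annotate_genes(coh$mutations, coh$genes, coh$reference)
  gm <- build_gene_motif_matrix(ann, unique(coh$truth$enriched$gene_id),
                                samples = names(coh$truth$subtype))
  bin <- as.matrix(gm$binary)
  enr <- coh$truth$enriched
  for (s in unique(enr$group)) {
    members <- names(coh$truth$subtype)[coh$truth$subtype == s]
    feats <- intersect(enr$feature[enr$group == s], colnames(bin))
    expect_true(all(bin[members, feats] == 1))
    expect_true(all(bin[setdiff(rownames(bin), members), feats] == 0))
  }
})

test_that("background gene counts follow the configured negative binomial", {
  coh <- get_small_cohort()
  ann <- get_small_annotated()
  gc_ <- build_gene_counts(ann, coh$genes)
  # restrict to non-driver genes: pure background
  bg <- gc_[!gc_$gene_id %in% coh$truth$driver_pool, ]
  fit <- fit_negbin(bg$k)
  cfg <- coh$config
  expect_lt(abs(fit$mean - cfg$background_nb_mean) / cfg$background_nb_mean,
            0.15)
})

test_that("cohort files round-trip and the truth sidecar stays separate", {
  coh <- get_small_cohort()
  td <- withr::local_tempdir()
  write_cohort(coh, td)
  expect_setequal(list.files(td),
                  c("reference.fa", "genes.gtf", "mutations.tsv",
                    "clinical.tsv", "truth.json"))
  muts <- read_mutations(file.path(td, "mutations.tsv"), quiet = TRUE)
  expect_equal(nrow(muts), nrow(coh$mutations))
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(length(truth$subtype), coh$config$n_samples)
  clin <- utils::read.delim(file.path(td, "clinical.tsv"))
  expect_setequal(names(clin),
                  c("sample_id", "sex", "country", "age",
                    "survival_time_days", "event"))
})
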