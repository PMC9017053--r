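# exhaustive two-sided Fisher oracle by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher's exact test matches enumeration on small tables", {
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    res <- fisher_exact(a, b, c, d)
    expect_equal(res$p_value, fisher_oracle(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("Fisher symmetry, degenerate margins and the worked example", {
  sym <- fisher_exact(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  # zero margin: no information
  zero <- fisher_exact(0, 0, 3, 4)
  expect_equal(zero$p_value, 1)
  expect_true(is.na(zero$odds_ratio))
  # a gene mutated in 42/44 subtype samples vs 144/489 elsewhere
  ex <- fisher_exact(42, 2, 144, 345)
  expect_equal(ex$odds_ratio, (42 * 345) / (2 * 144), tolerance = 1e-12)
  expect_equal(round(100 * 42 / 44), 95)
  expect_equal(round(100 * 144 / 489), 29)
  expect_lt(ex$p_value, 1e-10)
  expect_equal(ex$p_value, fisher_oracle(42, 2, 144, 345),
               tolerance = 1e-9)
  # swapping (subtype, rest) leaves the p-value unchanged
  sw <- fisher_exact(144, 345, 42, 2)
  expect_equal(sw$p_value, ex$p_value, tolerance = 1e-12)
})

test_that("subtype-vs-rest scan finds planted genes and keeps its bookkeeping", {
  coh <- get_small_cohort()
  ann <- get_small_annotated()
  gc_ <- build_gene_counts(ann, coh$genes)
  sg <- attr(gc_, "sample_gene")
  samples <- sort(unique(coh$mutations$sample_id))
  genes <- coh$genes$gene_id
  m <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(sg$sample_id, samples), match(sg$gene_id, genes))] <- 1L
  truth_asg <- data.frame(sample_id = names(coh$truth$subtype),
                          subtype = unname(coh$truth$subtype),
                          stringsAsFactors = FALSE)
  scan <- subtype_feature_scan(m, truth_asg)
  expect_equal(nrow(scan), length(genes) * length(unique(truth_asg$subtype)))
  # at the gene-motif level each subtype's planted features top its own
  # scan (driver genes are shared between subtypes by design, so the
  # gene-level scan is diluted; the motif context is what separates them)
  gm <- build_gene_motif_matrix(ann, coh$truth$driver_pool,
                                samples = samples)
  fscan <- subtype_feature_scan(as.matrix(gm$binary), truth_asg)
  enr <- coh$truth$enriched
  for (s in unique(enr$group)) {
    own <- enr$feature[enr$group == s]
    sub <- fscan[fscan$subtype == s, ]
    top <- sub$feature_id[order(sub$p_value)][seq_len(10)]
    expect_gt(length(intersect(top, own)), 5)
  }
  # a uniformly mutated feature is never significant
  m2 <- cbind(m, UNIFORM = 1L)
  m2[, "UNIFORM"] <- rep_len(c(1L, 0L), nrow(m2))
  scan2 <- subtype_feature_scan(m2, truth_asg)
  expect_true(all(scan2$p_value[scan2$feature_id == "UNIFORM"] > 0.01))
})

test_that("motif preference recovers the planted motif per subtype", {
  coh <- get_small_cohort()
  ann <- get_small_annotated()
  truth_asg <- data.frame(sample_id = names(coh$truth$subtype),
                          subtype = unname(coh$truth$subtype),
                          stringsAsFactors = FALSE)
  enr <- coh$truth$enriched
  # planted motifs are carried by ~80% of their subtype and are (near)
  # absent in the opposite super-cluster's subtypes
  sc_of <- function(lab) {
    coh$truth$supercluster[[which(coh$truth$subtype == lab)[1]]]
  }
  set.seed(17)
  for (i in sample(nrow(enr), 5)) {
    cand <- enr[i, ]
    mp <- motif_preference(ann, truth_asg, cand$gene_id)
    own <- mp[[cand$group]]$fractions[[cand$motif]]
    expect_gte(own, 0.5)
    other_sc <- names(mp)[vapply(names(mp), sc_of, 0L) != sc_of(cand$group)]
    for (s in other_sc) {
      expect_lte(mp[[s]]$fractions[[cand$motif]], 0.25)
    }
    expect_true(all(mp[[cand$group]]$fractions >= 0 &
                      mp[[cand$group]]$fractions <= 1))
  }
  # hand-built case: a subtype whose only mutations in a gene share one
  # class has that class as its unique dominant motif
  hand <- data.frame(sample_id = c("A1", "A2", "B1"), chrom = "chr1",
                     pos = 1:3, ref = "C", alt = "T", gene_id = "GX",
                     biotype = "coding", context = NA,
                     motif = c("A[C>T]G", "A[C>T]G", "T[C>G]C"),
                     stringsAsFactors = FALSE)
  asg2 <- data.frame(sample_id = c("A1", "A2", "B1"),
                     subtype = c("S1", "S1", "S2"),
                     stringsAsFactors = FALSE)
  mp2 <- motif_preference(hand, asg2, "GX")
  expect_identical(mp2$S1$dominant, "A[C>T]G")
  expect_identical(mp2$S2$dominant, "T[C>G]C")
})

test_that("consequence tables are column-stochastic percentages", {
  coh <- get_small_cohort()
  truth_asg <- data.frame(sample_id = names(coh$truth$subtype),
                          subtype = unname(coh$truth$subtype),
                          stringsAsFactors = FALSE)
  ct <- consequence_table(coh$mutations, truth_asg)
  expect_equal(unname(colSums(ct)), rep(100, ncol(ct)), tolerance = 0.1)
  # generator truth: in-gene mixture recovered within multinomial error
  cp <- coh$config$consequence_probs
  ing <- coh$mutations$consequence_type[
    coh$mutations$consequence_type != "intergenic_region"]
  obs <- table(ing)[names(cp)] / length(ing)
  expect_lt(max(abs(obs - cp), na.rm = TRUE), 0.02)
  # all-intron input concentrates every column
  m1 <- coh$mutations
  m1$consequence_type <- "intron_variant"
  ct1 <- consequence_table(m1, truth_asg)
  expect_true(all(ct1["intron_variant", ] == 100))
})

test_that("mutational load splits by biotype, conserves totals and flags hypermutation", {
  coh <- get_small_cohort()
  ann <- get_small_annotated()
  truth_asg <- data.frame(sample_id = names(coh$truth$subtype),
                          subtype = unname(coh$truth$subtype),
                          stringsAsFactors = FALSE)
  ml <- mutational_load(ann, truth_asg)
  expect_equal(ml$per_sample$total,
               ml$per_sample$coding + ml$per_sample$lncRNA)
  hyper <- paste0("T", coh$config$hyper_subtype)
  expect_true(ml$per_subtype$hyper_mutated[ml$per_subtype$subtype == hyper])
  expect_lte(sum(ml$per_subtype$hyper_mutated), 2)
  # single-subtype cohort: subtype mean equals cohort mean
  one <- truth_asg; one$subtype <- "ALL"
  ml1 <- mutational_load(ann, one)
  expect_equal(ml1$per_subtype$total_mean, mean(ml1$per_sample$total))
})

test_that("transcript enrichment detects the planted transcript bias", {
  coh <- get_small_cohort()
  truth_asg <- data.frame(sample_id = names(coh$truth$subtype),
                          subtype = unname(coh$truth$subtype),
                          stringsAsFactors = FALSE)
  te <- transcript_enrichment(coh$mutations, truth_asg)
  expect_false(is.null(te))
  expect_true(all(te$fractions >= 0 & te$fractions <= 1))
  # planted driver mutations favor each driver gene's first transcript
  first_tx <- paste0("TX", coh$truth$driver_pool, ".1")
  tx_obs <- table(coh$mutations$transcript_id)
  multi_tx_drivers <- intersect(first_tx, names(tx_obs))
  expect_gt(length(multi_tx_drivers), 0)
  # no transcript info -> skipped with warning
  m0 <- coh$mutations
  m0$transcript_id <- NULL
  expect_warning(out <- transcript_enrichment(m0, truth_asg), "skipped")
  expect_null(out)
})

test_that("hypergeometric over-representation matches direct summation", {
  universe <- paste0("g", 1:200)
  sets <- list(hit = universe[1:20], other = universe[101:130],
               tiny = universe[1:3])
  gl <- universe[1:15]
  res <- ora_hypergeometric(gl, sets, universe)
  expect_false("tiny" %in% res$set)  # below min size
  expect_identical(res$set[1], "hit")
  oracle <- sum(dhyper(15:15, 20, 180, 15)) +
    sum(dhyper(16:20, 20, 180, 15) * 0)  # overlap is 15 of 15
  direct <- phyper(14, 20, 180, 15, lower.tail = FALSE)
  expect_equal(res$p_value[res$set == "hit"], direct, tolerance = 1e-12)
  manual <- sum(vapply(15:15, function(x) dhyper(x, 20, 180, 15),
                       numeric(1)))
  expect_equal(direct, manual, tolerance = 1e-12)
  # null calibration: uniformly drawn gene lists are rarely significant
  set.seed(31)
  hits <- 0; trials <- 0
  many_sets <- lapply(1:40, function(i) sample(universe, 25))
  names(many_sets) <- paste0("s", 1:40)
  for (r in 1:10) {
    gl0 <- sample(universe, 15)
    res0 <- ora_hypergeometric(gl0, many_sets, universe)
    hits <- hits + sum(res0$p_value < 0.05)
    trials <- trials + nrow(res0)
  }
  expect_lt(hits / trials, 0.12)
  expect_error(ora_hypergeometric(gl, sets, character()), "empty universe")
})

test_that("GMT files round-trip", {
  tf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), tf)
  sets <- read_gmt(tf)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(names(sets), c("setA", "setB"))
})
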