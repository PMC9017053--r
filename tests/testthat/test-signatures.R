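planted_catalog <- function(n_samples = 120, k = 3, mean_load = 400,
                            seed = 13) {
  withr::with_seed(seed, {
    sigs <- t(vapply(seq_len(k), function(i) {
      as.numeric(rgamma(96, shape = 0.3))
    }, numeric(96)))
    sigs <- sigs / rowSums(sigs)          # k x 96, rows sum to 1
    expo <- matrix(rgamma(n_samples * k, shape = 1), n_samples, k)
    expo <- expo / rowSums(expo) * mean_load
    lambda <- expo %*% sigs               # samples x 96
    catalog <- matrix(rpois(length(lambda), lambda), n_samples, 96,
                      dimnames = list(paste0("S", seq_len(n_samples)),
                                      motif_classes()))
    list(catalog = catalog, signatures = t(sigs), exposures = expo)
  })
}

test_that("catalogs conserve counts and ignore mutation order and gene multiplicity", {
  ann <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2"),
    chrom = "chr1", pos = c(10L, 10L, 11L, 12L),
    ref = "C", alt = "T",
    gene_id = c("G1", "G2", "G1", NA),   # S1's mutation overlaps two genes
    motif = c("A[C>T]G", "A[C>T]G", "C[C>T]C", NA),
    stringsAsFactors = FALSE)
  cat96 <- build_catalog(ann)
  expect_equal(dim(cat96), c(2, 96))
  expect_equal(cat96["S1", "A[C>T]G"], 1)  # counted once, not per gene
  expect_equal(sum(cat96), 2)              # the NA-motif row is excluded
  shuffled <- build_catalog(ann[c(3, 1, 4, 2), ])
  expect_equal(cat96, shuffled[rownames(cat96), ])

  coh <- get_small_cohort()
  annc <- get_small_annotated()
  cc <- build_catalog(annc)
  key <- paste(annc$sample_id, annc$chrom, annc$pos, annc$alt)
  distinct <- annc[!duplicated(key), ]
  expect_equal(sum(cc), sum(!is.na(distinct$motif)))
})

test_that("rank-1 catalogs factor exactly at k = 1", {
  withr::with_seed(2, {
    w <- rgamma(96, 1); h <- rgamma(50, 2) * 20
  })
  catalog <- outer(h, w)   # samples x 96
  colnames(catalog) <- motif_classes()
  rownames(catalog) <- paste0("S", 1:50)
  fit <- nmf_decompose(catalog, k = 1, n_restarts = 3, seed = 1)
  recon <- fit$exposures %*% t(fit$signatures)
  expect_lt(sqrt(sum((catalog - recon)^2)) / sqrt(sum(catalog^2)), 1e-6)
  expect_equal(unname(colSums(fit$signatures)), 1, tolerance = 1e-9)
})

test_that("planted signatures are recovered at the true k", {
  pc <- planted_catalog()
  fit <- nmf_decompose(pc$catalog, k = 3, n_restarts = 8, seed = 3)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  match_cos <- vapply(seq_len(3), function(j) {
    max(vapply(seq_len(3), function(i) {
      cos(pc$signatures[, j], fit$signatures[, i])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(match_cos >= 0.95))
  # more iterations never worsen the objective
  fit_short <- nmf_decompose(pc$catalog, k = 3, n_restarts = 2, seed = 5,
                             max_iter = 30)
  fit_long <- nmf_decompose(pc$catalog, k = 3, n_restarts = 2, seed = 5,
                            max_iter = 400)
  expect_lte(fit_long$objective, fit_short$objective + 1e-6)
  expect_error(nmf_decompose(pc$catalog * 0, 2), "all-zero")
})

test_that("scaling the catalog scales exposures, not signatures", {
  pc <- planted_catalog(n_samples = 60, seed = 21)
  f1 <- nmf_decompose(pc$catalog, k = 2, n_restarts = 4, seed = 9)
  f2 <- nmf_decompose(pc$catalog * 3, k = 2, n_restarts = 4, seed = 9)
  # match columns by cosine before comparing
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (j in 1:2) {
    i <- which.max(vapply(1:2, function(i) {
      cos(f1$signatures[, j], f2$signatures[, i])
    }, numeric(1)))
    expect_gt(cos(f1$signatures[, j], f2$signatures[, i]), 0.99)
    expect_equal(sum(f2$exposures[, i]) / sum(f1$exposures[, j]), 3,
                 tolerance = 0.05)
  }
})

test_that("stability-based selection chooses the planted signature count", {
  pc <- planted_catalog(n_samples = 120, seed = 17)
  sel <- select_k(pc$catalog, k_range = 2:5, n_restarts = 6, seed = 11)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$diagnostics), 4)
  expect_true(all(c("stability", "reconstruction_error") %in%
                    names(sel$diagnostics)))
  # k = 1 stability is 1 by construction
  sel1 <- select_k(pc$catalog, k_range = 1, n_restarts = 4, seed = 2)
  expect_equal(sel1$diagnostics$stability, 1.0)
})

test_that("reference matching pairs identical sets and flags combinations", {
  pc <- planted_catalog(n_samples = 80, seed = 23)
  sig <- pc$signatures
  colnames(sig) <- paste0("sig", 1:3)
  rownames(sig) <- motif_classes()
  res <- match_reference(sig, sig)
  expect_equal(res$pairing$signature, res$pairing$reference)
  expect_equal(res$pairing$r, rep(1, 3), tolerance = 1e-12)
  # noise perturbation keeps high correlation
  noisy <- sig + matrix(abs(rnorm(96 * 3, sd = 0.002)), 96, 3)
  rownames(noisy) <- motif_classes()
  res2 <- match_reference(sig, noisy)
  expect_true(all(res2$pairing$r > 0.95))
  # a reference built as a blend of two signatures is flagged
  blend <- cbind(mix = 0.5 * (sig[, 1] + sig[, 3]))
  rownames(blend) <- motif_classes()
  res3 <- match_reference(sig, blend)
  expect_false(is.null(res3$combinations))
  expect_true(any(res3$combinations$reference == "mix"))
  # channel-order mismatch is a hard error
  bad <- sig; rownames(bad) <- rev(rownames(bad))
  expect_error(match_reference(sig, bad), "row order")
})

test_that("per-subtype exposures are normalized means", {
  pc <- planted_catalog(n_samples = 60, seed = 29)
  fit <- nmf_decompose(pc$catalog, k = 2, n_restarts = 4, seed = 7)
  asg <- data.frame(sample_id = rownames(fit$exposures),
                    subtype = rep(c("SC1", "SC2"), each = 30),
                    stringsAsFactors = FALSE)
  eb <- exposures_by_subtype(fit$exposures, asg)
  expect_equal(unname(rowSums(eb$mean)), c(1, 1), tolerance = 1e-9)
  one <- asg; one$subtype <- "ALL"
  eb1 <- exposures_by_subtype(fit$exposures, one)
  rs <- rowSums(fit$exposures); prop <- fit$exposures / rs
  expect_equal(unname(eb1$mean["ALL", ]), unname(colMeans(prop)),
               tolerance = 1e-12)
})
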