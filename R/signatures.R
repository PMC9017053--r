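#' Build the samples x 96 mutation catalog
#'
#' Counts each distinct mutation (sample, chrom, pos, alt) once per sample
#' in its trinucleotide substitution class, regardless of how many genes it
#' overlaps. By default all context-available mutations contribute
#' (genome-wide catalog); set `gene_linked = TRUE` to restrict to mutations
#' inside gene bodies.
#'
#' @param annotated Data.frame from [annotate_genes()] (rows with `NA`
#'   motif are skipped).
#' @param samples Optional row universe; defaults to observed samples.
#' @param gene_linked Restrict to in-gene mutations (default FALSE).
#' @return Integer matrix samples x 96, columns in [motif_classes()] order.
#' @export
build_catalog <- function(annotated, samples = NULL, gene_linked = FALSE) {
  ann <- annotated[!is.na(annotated$motif), , drop = FALSE]
  if (gene_linked) ann <- ann[!is.na(ann$gene_id), , drop = FALSE]
  # one count per distinct mutation even if annotated to several genes
  key <- paste(ann$sample_id, ann$chrom, ann$pos, ann$alt, sep = "\r")
  ann <- ann[!duplicated(key), , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(annotated$sample_id))
  classes <- motif_classes()
  cat96 <- matrix(0L, nrow = length(samples), ncol = 96,
                  dimnames = list(samples, classes))
  if (nrow(ann) > 0) {
    tab <- table(factor(ann$sample_id, levels = samples),
                 factor(ann$motif, levels = classes))
    cat96[] <- as.integer(tab)
  }
  cat96
}

kl_divergence <- function(v, wh) {
  # generalized KL divergence D(V || WH), with 0 log 0 = 0
  pos <- v > 0
  sum(v[pos] * log(v[pos] / wh[pos])) - sum(v) + sum(wh)
}

nmf_kl_once <- function(v, k, max_iter, tol) {
  # v: 96 x S, factorize v ~ w %*% h with w 96 x k (signatures), h k x S
  d <- nrow(v); s <- ncol(v)
  w <- matrix(stats::runif(d * k, 0.1, 1), d, k)
  h <- matrix(stats::runif(k * s, 0.1, 1), k, s)
  eps <- .Machine$double.eps
  obj <- Inf
  for (it in seq_len(max_iter)) {
    wh <- w %*% h + eps
    h <- h * (t(w) %*% (v / wh)) / (colSums(w) + eps)
    wh <- w %*% h + eps
    w <- w * ((v / wh) %*% t(h)) / matrix(rowSums(h) + eps, d, k,
                                          byrow = TRUE)
    if (it %% 10 == 0 || it == max_iter) {
      new_obj <- kl_divergence(v, w %*% h + eps)
      if (is.finite(obj) && abs(obj - new_obj) < tol * max(1, abs(obj))) {
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
  }
  # column-stochastic signatures; rescale exposures compensatingly
  cs <- colSums(w)
  cs[cs == 0] <- 1
  w <- sweep(w, 2, cs, "/")
  h <- sweep(h, 1, cs, "*")
  list(w = w, h = h, objective = kl_divergence(v, w %*% h + eps))
}

#' NMF decomposition of a mutation catalog
#'
#' Factorizes the catalog into `k` nonnegative signatures (96-dimensional,
#' column-stochastic) and per-sample exposures by multiplicative updates
#' under the generalized Kullback-Leibler objective (the standard choice
#' for Poisson-distributed mutation counts). The best of `n_restarts`
#' random initializations is kept.
#'
#' @param catalog Samples x 96 nonnegative matrix from [build_catalog()].
#' @param k Number of signatures (1 <= k <= min(96, n_samples)).
#' @param n_restarts Random restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter,tol Update-loop controls.
#' @return List of class `"signature_set"`: `signatures` (96 x k,
#'   columns sum to 1), `exposures` (samples x k), `k`, `objective`
#'   (best generalized KL divergence), `objectives` (per restart).
#' @export
nmf_decompose <- function(catalog, k, n_restarts = 10, seed = 1L,
                          max_iter = 500, tol = 1e-7) {
  v <- t(as.matrix(catalog))   # 96 x S
  if (all(v == 0)) stop("all-zero catalog: nothing to decompose")
  if (k < 1 || k > min(nrow(v), ncol(v))) {
    stop("k must be between 1 and min(96, n_samples)")
  }
  runs <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      nmf_kl_once(v, k, max_iter, tol)
    })
  })
  objs <- vapply(runs, function(r) r$objective, numeric(1))
  best <- runs[[which.min(objs)]]
  sig <- best$w
  colnames(sig) <- paste0("signature", seq_len(k))
  rownames(sig) <- rownames(v)
  expo <- t(best$h)
  dimnames(expo) <- list(colnames(v), colnames(sig))
  structure(list(signatures = sig, exposures = expo, k = k,
                 objective = min(objs), objectives = objs),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature set: k =", x$k, "signatures over",
      nrow(x$exposures), "samples; best KL objective",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}

cosine_sim <- function(a, b) {
  as.numeric(crossprod(a, b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Choose the number of signatures by restart stability
#'
#' For each candidate `k`, runs `n_restarts` NMF restarts, matches every
#' restart's signatures to the best restart's by greedy cosine similarity,
#' and scores the resulting signature clusters by their mean silhouette
#' width under cosine distance. A stable `k` reproduces essentially the
#' same signatures from every random start (silhouette near 1); an
#' over-fitted `k` splits processes inconsistently. The chosen `k` is the
#' largest candidate whose stability reaches `stability_threshold`
#' (default 0.8); the full per-k diagnostics (stability, reconstruction
#' error) are returned so the choice can be overridden.
#'
#' @param catalog Samples x 96 matrix.
#' @param k_range Candidate counts, e.g. `2:8`.
#' @param n_restarts Restarts per k (default 10).
#' @param seed Integer seed.
#' @param stability_threshold Minimum mean silhouette (default 0.8).
#' @param ... Passed to [nmf_decompose()].
#' @return List: `k` (chosen), `diagnostics` (data.frame k, stability,
#'   reconstruction_error), `fits` (per-k best `"signature_set"`).
#' @export
select_k <- function(catalog, k_range, n_restarts = 10, seed = 1L,
                     stability_threshold = 0.8, ...) {
  v <- t(as.matrix(catalog))
  fits <- list()
  diag_rows <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    runs <- withr::with_seed(seed + ki, {
      lapply(seq_len(n_restarts), function(i) {
        nmf_kl_once(v, k, max_iter = 500, tol = 1e-7)
      })
    })
    objs <- vapply(runs, function(r) r$objective, numeric(1))
    best <- runs[[which.min(objs)]]
    if (k == 1 || n_restarts < 2) {
      stability <- 1.0
    } else {
      # pool all restart signatures, cluster by greedy match to the best run
      members <- list()
      for (r in runs) {
        assigned <- greedy_match(best$w, r$w)
        for (j in seq_len(k)) {
          members[[length(members) + 1]] <-
            list(cluster = j, sig = r$w[, assigned[j]])
        }
      }
      stability <- mean_silhouette_cosine(members, k)
    }
    fit <- best
    sig <- fit$w
    colnames(sig) <- paste0("signature", seq_len(k))
    rownames(sig) <- rownames(v)
    expo <- t(fit$h)
    dimnames(expo) <- list(colnames(v), colnames(sig))
    fits[[as.character(k)]] <- structure(
      list(signatures = sig, exposures = expo, k = k,
           objective = min(objs), objectives = objs),
      class = "signature_set")
    recon <- sig %*% t(expo)
    diag_rows[[ki]] <- data.frame(
      k = k, stability = stability,
      reconstruction_error = sqrt(sum((v - recon)^2)) / sqrt(sum(v^2)))
  }
  diagnostics <- do.call(rbind, diag_rows)
  stable <- diagnostics$k[diagnostics$stability >= stability_threshold]
  chosen <- if (length(stable) > 0) max(stable) else min(k_range)
  list(k = chosen, diagnostics = diagnostics, fits = fits)
}

#' Greedy one-to-one matching of signature columns by cosine similarity
#' @noRd
greedy_match <- function(ref, cand) {
  k <- ncol(ref)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- cosine_sim(ref[, i], cand[, j])
  }
  assigned <- integer(k)
  taken <- logical(k)
  for (step in seq_len(k)) {
    sim_masked <- sim
    sim_masked[assigned > 0, ] <- -Inf
    sim_masked[, taken] <- -Inf
    pos <- arrayInd(which.max(sim_masked), dim(sim_masked))
    assigned[pos[1]] <- pos[2]
    taken[pos[2]] <- TRUE
  }
  assigned
}

mean_silhouette_cosine <- function(members, k) {
  sigs <- vapply(members, function(m) m$sig, numeric(length(members[[1]]$sig)))
  cl <- vapply(members, function(m) m$cluster, 0L)
  n <- length(cl)
  # pairwise cosine distances
  norms <- sqrt(colSums(sigs^2))
  sim <- crossprod(sigs) / outer(norms, norms)
  d <- 1 - sim
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Match extracted signatures to a reference set by Pearson correlation
#'
#' Computes the full Pearson correlation matrix between extracted and
#' reference signatures (rows must share the canonical 96-class order,
#' validated by name) and a greedy best pairing. Each reference signature
#' is additionally regressed on every pair of extracted signatures to flag
#' cases where a nonnegative linear combination of two extracted signatures
#' explains it better than any single one.
#'
#' @param signatures 96 x k matrix (e.g. `$signatures` of a fit).
#' @param reference 96 x m reference matrix with rownames in
#'   [motif_classes()] order.
#' @param r2_gain Minimum R-squared improvement for a combination flag
#'   (default 0.05).
#' @return List: `correlation` (k x m), `pairing` (data.frame signature,
#'   reference, r), `combinations` (data.frame of flagged two-signature
#'   matches).
#' @export
match_reference <- function(signatures, reference, r2_gain = 0.05) {
  if (is.null(rownames(signatures)) || is.null(rownames(reference)) ||
      !identical(rownames(signatures), rownames(reference))) {
    stop("signature and reference matrices must share identical ",
         "96-class row order (check rownames)")
  }
  rmat <- stats::cor(signatures, reference)
  k <- ncol(signatures); m <- ncol(reference)
  pairing <- list()
  taken_ref <- logical(m)
  taken_sig <- logical(k)
  for (step in seq_len(min(k, m))) {
    tmp <- rmat
    tmp[taken_sig, ] <- -Inf
    tmp[, taken_ref] <- -Inf
    pos <- arrayInd(which.max(tmp), dim(tmp))
    pairing[[step]] <- data.frame(
      signature = colnames(signatures)[pos[1]],
      reference = colnames(reference)[pos[2]],
      r = rmat[pos[1], pos[2]],
      stringsAsFactors = FALSE)
    taken_sig[pos[1]] <- TRUE
    taken_ref[pos[2]] <- TRUE
  }
  r2_of <- function(y, x) {
    f <- stats::lm.fit(cbind(1, x), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  combos <- list()
  if (k >= 2) {
    for (j in seq_len(m)) {
      y <- reference[, j]
      best_single <- max(vapply(seq_len(k), function(i) {
        r2_of(y, signatures[, i, drop = FALSE])
      }, numeric(1)))
      for (i1 in seq_len(k - 1)) for (i2 in (i1 + 1):k) {
        r2 <- r2_of(y, signatures[, c(i1, i2), drop = FALSE])
        if (r2 > best_single + r2_gain) {
          combos[[length(combos) + 1]] <- data.frame(
            reference = colnames(reference)[j],
            signature_a = colnames(signatures)[i1],
            signature_b = colnames(signatures)[i2],
            r_squared = r2, best_single_r_squared = best_single,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(correlation = rmat,
       pairing = do.call(rbind, pairing),
       combinations = if (length(combos) > 0) do.call(rbind, combos)
                      else NULL)
}

#' Mean signature exposures per subtype
#'
#' Exposures are first normalized per sample to proportions (each sample's
#' exposures sum to 1), then averaged within each subtype.
#'
#' @param exposures Samples x k matrix (`$exposures`).
#' @param assignment Data.frame (sample_id, subtype) from
#'   [assign_subtypes()].
#' @return List: `mean` and `sd`, each subtypes x k.
#' @export
exposures_by_subtype <- function(exposures, assignment) {
  idx <- match(rownames(exposures), assignment$sample_id)
  if (anyNA(idx)) stop("exposure rows missing from subtype assignment")
  subtype <- assignment$subtype[idx]
  rs <- rowSums(exposures)
  rs[rs == 0] <- 1
  prop <- exposures / rs
  labs <- sort(unique(subtype))
  mu <- t(vapply(labs, function(s) colMeans(prop[subtype == s, ,
                                                 drop = FALSE]),
                 numeric(ncol(exposures))))
  sdv <- t(vapply(labs, function(s) apply(prop[subtype == s, ,
                                               drop = FALSE], 2,
                                          stats::sd),
                  numeric(ncol(exposures))))
  rownames(mu) <- rownames(sdv) <- labs
  list(mean = mu, sd = sdv)
}
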