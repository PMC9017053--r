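#' Cullen-Frey skewness-kurtosis diagnostic
#'
#' Computes the sample skewness and excess kurtosis of a count vector
#' together with a bootstrap cloud of the same pair, and the theoretical
#' loci of common candidate families (Poisson, negative binomial, normal,
#' lognormal, gamma, beta). The result is a diagnostic report for choosing a
#' candidate family; it makes no decision itself — pair it with
#' [cvm_statistic()] on the fitted candidates.
#'
#' Skewness is \eqn{m_3 / m_2^{3/2}} and excess kurtosis
#' \eqn{m_4 / m_2^2 - 3} with central sample moments \eqn{m_j}.
#'
#' @param data Nonnegative integer vector, length >= 4, non-constant.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list of class `"cullen_frey"`: `skewness`, `kurtosis` (excess),
#'   `bootstrap_points` (n_boot x 2 matrix), `theoretical` (data.frame of
#'   family loci evaluated at moment-matched parameters).
#' @export
cullen_frey <- function(data, n_boot = 100, seed = NULL) {
  if (length(data) < 4) stop("need at least 4 observations")
  if (any(data < 0)) stop("counts must be nonnegative")
  if (stats::var(data) == 0) {
    stop("degenerate data: zero variance, no distribution shape to assess")
  }
  sk <- function(x) {
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    c(skewness = mean((x - m)^3) / s^3,
      kurtosis = mean((x - m)^4) / s^4 - 3)
  }
  obs <- sk(data)
  boot_fun <- function() {
    t(replicate(n_boot, sk(sample(data, replace = TRUE))))
  }
  boot <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())

  m <- mean(data); v <- stats::var(data)
  theo <- list(poisson = c(1 / sqrt(m), 1 / m))
  if (v > m) {
    size <- m^2 / (v - m); p <- size / (size + m)
    theo$negative_binomial <- c((2 - p) / sqrt(size * (1 - p)),
                                6 / size + p^2 / (size * (1 - p)))
  }
  theo$normal <- c(0, 0)
  if (all(data > 0)) {
    s2 <- log(1 + v / m^2)
    theo$lognormal <- c((exp(s2) + 2) * sqrt(exp(s2) - 1),
                        exp(4 * s2) + 2 * exp(3 * s2) + 3 * exp(2 * s2) - 6)
  }
  shape <- m^2 / v
  theo$gamma <- c(2 / sqrt(shape), 6 / shape)
  theoretical <- data.frame(
    family = names(theo),
    skewness = vapply(theo, `[`, 0, 1L),
    kurtosis = vapply(theo, `[`, 0, 2L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(skewness = unname(obs["skewness"]),
                 kurtosis = unname(obs["kurtosis"]),
                 bootstrap_points = boot,
                 theoretical = theoretical,
                 n = length(data)),
            class = "cullen_frey")
}

#' @export
print.cullen_frey <- function(x, ...) {
  cat(sprintf("Cullen-Frey diagnostic (n = %d, %d bootstrap resamples)\n",
              x$n, nrow(x$bootstrap_points)))
  cat(sprintf("  skewness %.3f, excess kurtosis %.3f\n",
              x$skewness, x$kurtosis))
  print(x$theoretical, digits = 3)
  invisible(x)
}

#' Fit a negative-binomial background to per-gene counts
#'
#' Maximum-likelihood fit of the negative binomial in the (r, p)
#' parameterization with pmf \eqn{C(i+r-1, r-1) p^r q^i} on support
#' \eqn{i = 0, 1, \dots} and mean \eqn{r q / p} (q = 1 - p). The mean MLE is
#' the sample mean; the size r is profiled by 1-D optimization of the
#' log-likelihood, initialized at the method-of-moments value. When the data
#' are not overdispersed (variance <= mean) the NB size diverges, so the fit
#' falls back to Poisson with a warning.
#'
#' @param data Nonnegative integer counts, length >= 2.
#' @return List of class `"negbin_params"`: `r`, `p`, `q`, `mean`,
#'   `distribution` ("nbinom" or "poisson" fallback with `lambda`),
#'   `loglik`.
#' @export
fit_negbin <- function(data) {
  if (length(data) < 2) stop("need at least 2 observations")
  if (any(data < 0)) stop("counts must be nonnegative")
  m <- mean(data); v <- stats::var(data)
  if (v <= m) {
    warning("variance <= mean: no overdispersion, falling back to Poisson")
    return(structure(list(distribution = "poisson", lambda = m, mean = m,
                          loglik = sum(stats::dpois(data, m, log = TRUE))),
                     class = "negbin_params"))
  }
  nll <- function(log_size) {
    -sum(stats::dnbinom(data, size = exp(log_size), mu = m, log = TRUE))
  }
  init <- log(m^2 / (v - m))
  opt <- stats::optim(init, nll, method = "Brent",
                      lower = init - 15, upper = init + 15)
  if (opt$convergence != 0) {
    stop("negative-binomial MLE did not converge: ",
         paste(utils::capture.output(str(opt)), collapse = " "))
  }
  r <- exp(opt$par)
  p <- r / (r + m)
  structure(list(distribution = "nbinom", r = r, p = p, q = 1 - p,
                 mean = m, loglik = -opt$value),
            class = "negbin_params")
}

#' Upper-tail negative-binomial probability P(X >= k)
#'
#' The per-gene P-value: probability, under the pooled background fit, of
#' observing at least `k` mutated samples. Computed as `1 - CDF(k - 1)` via
#' the survival function (the textbook term-by-term sum of the pmf from k
#' upward is algebraically identical and is used as the oracle in the test
#' suite).
#'
#' @param k Observed count(s), >= 0.
#' @param params `"negbin_params"` from [fit_negbin()].
#' @return P-value(s) in `[0, 1]`; `k = 0` gives exactly 1.
#' @export
negbin_tail_p <- function(k, params) {
  if (!inherits(params, "negbin_params")) stop("params must be negbin_params")
  if (any(k < 0)) stop("k must be nonnegative")
  if (params$distribution == "poisson") {
    return(ifelse(k == 0, 1,
                  stats::ppois(k - 1, params$lambda, lower.tail = FALSE)))
  }
  ifelse(k == 0, 1, stats::pnbinom(k - 1, size = params$r, prob = params$p,
                                   lower.tail = FALSE))
}

#' Beta-binomial log pmf
#' @noRd
dbetabinom_log <- function(i, n, alpha, beta) {
  lchoose(n, i) + lbeta(i + alpha, n - i + beta) - lbeta(alpha, beta)
}

#' Fit a beta-binomial background to per-gene-motif counts
#'
#' Maximum-likelihood fit of the beta-binomial on counts `k` out of a common
#' cohort size `n`: the per-sample mutation probability is Beta(alpha, beta)
#' distributed and the pmf is \eqn{C(n,i) B(i+\alpha, n-i+\beta)/B(\alpha,\beta)}.
#' Optimization is over (log alpha, log beta) with method-of-moments
#' initialization. Data whose sample variance does not exceed the binomial
#' variance carry no overdispersion signal; the fit then falls back to a
#' plain binomial with a warning.
#'
#' @param k Integer counts, all `<= n`, with at least 2 distinct values.
#' @param n Cohort size (scalar).
#' @return List of class `"betabin_params"`: `n`, `alpha`, `beta`,
#'   `distribution` ("betabinom" or "binomial" fallback with `prob`),
#'   `loglik`.
#' @export
fit_betabin <- function(k, n) {
  if (any(k < 0) || any(k > n)) stop("all k must satisfy 0 <= k <= n")
  if (length(unique(k)) < 2) {
    stop("degenerate data: all counts identical, cannot fit a distribution")
  }
  phat <- mean(k) / n
  v <- stats::var(k)
  vbin <- n * phat * (1 - phat)
  if (v <= vbin) {
    warning("variance at or below binomial: no overdispersion, ",
            "falling back to binomial")
    return(structure(list(distribution = "binomial", n = n, prob = phat,
                          loglik = sum(stats::dbinom(k, n, phat,
                                                     log = TRUE))),
                     class = "betabin_params"))
  }
  # method of moments: rho = intraclass correlation
  rho <- (v / vbin - 1) / (n - 1)
  rho <- min(max(rho, 1e-6), 1 - 1e-6)
  s0 <- (1 - rho) / rho   # alpha + beta
  init <- log(c(alpha = phat * s0, beta = (1 - phat) * s0))
  nll <- function(par) {
    -sum(dbetabinom_log(k, n, exp(par[1]), exp(par[2])))
  }
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0) {
    stop("beta-binomial MLE did not converge (code ", opt$convergence, ")")
  }
  structure(list(distribution = "betabinom", n = n,
                 alpha = unname(exp(opt$par[1])),
                 beta = unname(exp(opt$par[2])),
                 loglik = -opt$value),
            class = "betabin_params")
}

#' Upper-tail beta-binomial probability P(X >= k)
#'
#' The per-gene-motif P-value under the pooled beta-binomial background.
#' Computed in log space as `1 - sum_{i < k} pmf(i)`, with the complementary
#' direct sum used when `k > n/2` to avoid cancellation.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param params `"betabin_params"` from [fit_betabin()].
#' @return P-value(s) in `[0, 1]`; `k = 0` gives exactly 1.
#' @export
betabin_tail_p <- function(k, params) {
  if (!inherits(params, "betabin_params")) stop("params must be betabin_params")
  n <- params$n
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (params$distribution == "binomial") {
    return(ifelse(k == 0, 1, stats::pbinom(k - 1, n, params$prob,
                                           lower.tail = FALSE)))
  }
  logp <- dbetabinom_log(0:n, n, params$alpha, params$beta)
  pmf <- exp(logp)
  # direct upper sum of positive terms: free of the cancellation that
  # 1 - CDF(k-1) suffers when the tail is tiny
  vapply(k, function(kk) {
    if (kk == 0) return(1)
    min(1, sum(pmf[(kk + 1):(n + 1)]))
  }, numeric(1))
}

#' Cramer-von Mises statistic against a fitted CDF
#'
#' \eqn{\omega^2 = 1/(12m) + \sum_i (F(x_{(i)}) - (2i-1)/(2m))^2} over the
#' sorted sample. Used to rank candidate background families (lower is a
#' better fit). For discrete fitted distributions this is the usual
#' plug-in version evaluated at the fitted CDF.
#'
#' @param data Numeric sample.
#' @param fitted_cdf Function: vectorized CDF of the fitted candidate.
#' @return The statistic (nonnegative scalar).
#' @export
cvm_statistic <- function(data, fitted_cdf) {
  x <- sort(data)
  m <- length(x)
  u <- fitted_cdf(x)
  1 / (12 * m) + sum((u - (2 * seq_len(m) - 1) / (2 * m))^2)
}

#' Significance results for genes under the pooled negative-binomial model
#'
#' Fits one negative binomial across all genes' mutated-sample counts and
#' assigns each gene the upper-tail probability of its own count under that
#' pooled background. No multiple-testing correction is applied to the
#' significance call (raw `p < threshold`, strict); Benjamini-Hochberg
#' q-values are reported alongside for transparency.
#'
#' @param gene_counts Data.frame from [build_gene_counts()].
#' @param threshold Significance threshold on the raw P-value (default 0.01).
#' @param biotype Optional filter, e.g. `"coding"`, applied to the
#'   *reported* genes; the background is always fitted across all genes
#'   (coding and lncRNA pooled), which stabilizes the null against the
#'   handful of highly mutated genes.
#' @param trim Fraction of the largest counts excluded from the background
#'   fit (default 0.05), for the same reason as in
#'   [gene_motif_significance()]: the heavily mutated genes the test is
#'   meant to flag would otherwise fatten their own null.
#' @return Data.frame (feature_id, k, p_value, q_value, significant), ranked
#'   by ascending p; the fit is attached as attribute `"fit"`.
#' @export
gene_significance <- function(gene_counts, threshold = 0.01,
                              biotype = NULL, trim = 0.05) {
  k_fit <- gene_counts$k
  if (trim > 0) {
    k_fit <- k_fit[k_fit <= stats::quantile(k_fit, 1 - trim)]
  }
  fit <- fit_negbin(k_fit)
  gc <- gene_counts
  if (!is.null(biotype)) gc <- gc[gc$biotype %in% biotype, , drop = FALSE]
  p <- negbin_tail_p(gc$k, fit)
  out <- data.frame(feature_id = gc$gene_id, k = gc$k, p_value = p,
                    q_value = stats::p.adjust(p, "BH"),
                    significant = p < threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Significance results for gene-motifs under the pooled beta-binomial model
#'
#' Fits one beta-binomial across all gene-motif distinct-sample counts
#' (typically restricted to the significant-gene set) and assigns each
#' feature the upper tail of its count.
#'
#' The background is fitted on the count distribution after excluding the
#' top `trim` fraction of counts (default 5%): the pooled histogram mixes
#' the background bulk with the truly enriched features the test is meant
#' to find, and an untrimmed maximum-likelihood fit lets that enriched
#' upper tail fatten its own null (the two-parameter beta-binomial absorbs
#' it by driving alpha toward zero). Trimming restricts the fit to the
#' background bulk; P-values are then evaluated for all features. Set
#' `trim = 0` for the untrimmed pooled fit.
#'
#' @param count_table Data.frame (`$count_table` of
#'   [build_gene_motif_matrix()]) with columns `feature`, `k`, `n`.
#' @param threshold Raw-P significance threshold (default 0.01).
#' @param trim Fraction of the largest counts excluded from the background
#'   fit (default 0.05).
#' @return Data.frame as in [gene_significance()] with attribute `"fit"`.
#' @export
gene_motif_significance <- function(count_table, threshold = 0.01,
                                    trim = 0.05) {
  n <- unique(count_table$n)
  if (length(n) != 1) stop("count table must have a single cohort size n")
  k_fit <- count_table$k
  if (trim > 0) {
    k_fit <- k_fit[k_fit <= stats::quantile(k_fit, 1 - trim)]
  }
  fit <- fit_betabin(k_fit, n)
  p <- betabin_tail_p(count_table$k, fit)
  out <- data.frame(feature_id = count_table$feature, k = count_table$k,
                    p_value = p, q_value = stats::p.adjust(p, "BH"),
                    significant = p < threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Select significant features
#'
#' Strict threshold (`p < threshold`, a feature at exactly the threshold is
#' excluded), ranked ascending by P-value.
#'
#' @param results Data.frame with columns `feature_id` and `p_value`.
#' @param threshold Default 0.01.
#' @return Character vector of significant feature ids, best first.
#' @export
select_significant <- function(results, threshold = 0.01) {
  sel <- results[results$p_value < threshold, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  sel$feature_id
}
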