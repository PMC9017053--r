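#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function \eqn{S(t) = \prod_{t_i \le t}
#' (1 - d_i / n_i)} over the distinct event times, with censored
#' observations reducing the risk set only. Ties at an event time are
#' handled by the simultaneous-event convention (all deaths at a time are
#' removed in one factor). The variance is Greenwood's formula. Computation
#' is delegated to [survival::survfit]; the returned object exposes the
#' curve components directly.
#'
#' @param time Nonnegative follow-up times (days).
#' @param event Event indicators: 1 = death observed, 0 = censored.
#' @return List of class `"km_curve"`: `time` (event times), `n_risk`,
#'   `n_event`, `surv`, `greenwood_var`, `n`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative survival time")
  if (length(time) < 1) stop("need at least one record")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  if (!any(keep)) {
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0),
                          greenwood_var = numeric(0), n = length(time)),
                     class = "km_curve"))
  }
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d))); the final term is
  # undefined when everyone at risk dies (S = 0), reported as 0 there
  nr <- fit$n.risk[keep]
  ne <- fit$n.event[keep]
  sv <- fit$surv[keep]
  term <- ifelse(nr > ne, ne / (nr * (nr - ne)), Inf)
  gv <- sv^2 * cumsum(term)
  gv[sv == 0] <- 0
  structure(list(time = fit$time[keep],
                 n_risk = nr,
                 n_event = ne,
                 surv = sv,
                 greenwood_var = gv,
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve over", x$n, "subjects,",
      length(x$time), "distinct event times\n")
  if (length(x$time) > 0) {
    print(utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                                 n_event = x$n_event, surv = x$surv), 10),
          digits = 4)
  }
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#' @param curve A `"km_curve"`.
#' @param t Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    below <- curve$time <= tt
    if (!any(below)) 1 else curve$surv[max(which(below))]
  }, numeric(1))
}

#' k-group log-rank test
#'
#' Compares survival distributions across groups using observed-minus-
#' expected event counts with the hypergeometric variance at each event
#' time (delegated to [survival::survdiff]); the statistic is chi-square
#' distributed with `k - 1` degrees of freedom under the null. Empty groups
#' are excluded with a warning.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (factor or character), one per record.
#' @param flag_threshold P-values below this are flagged in the result
#'   (default 1e-4); the flag is reported, never used as a filter.
#' @return List of class `"logrank_test"`: `chisq`, `df`, `p_value`,
#'   `observed`, `expected` (per group), `flagged`.
#' @export
logrank_test <- function(time, event, group, flag_threshold = 1e-4) {
  group <- as.character(group)
  counts <- table(group)
  if (length(counts) < 2) stop("need at least 2 non-empty groups")
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
    keep <- !group %in% empty
    time <- time[keep]; event <- event[keep]; group <- group[keep]
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  p <- stats::pchisq(fit$chisq, df = df, lower.tail = FALSE)
  structure(list(chisq = unname(fit$chisq), df = df, p_value = p,
                 observed = fit$obs, expected = fit$exp,
                 groups = sub("^group=", "", names(fit$n)),
                 flagged = p < flag_threshold),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.4g on %d df, p = %.4g%s\n",
              x$chisq, x$df, x$p_value,
              if (x$flagged) "  [p < 1e-4]" else ""))
  invisible(x)
}

#' Per-subtype clinical composition summary
#'
#' Percentage tables of sex and country per subtype (denominators reported;
#' missing values excluded per field with counts) plus per-subtype age
#' summaries and histogram counts.
#'
#' @param clinical Data.frame with `sample_id` and any of `sex`, `country`,
#'   `age`.
#' @param assignment Data.frame (sample_id, subtype).
#' @param age_breaks Histogram break points for age (default every 10
#'   years, 0-110).
#' @return List with elements `sex`, `country` (each a list of `percent`
#'   matrix, `denominator`, `n_missing`), and `age` (summary data.frame and
#'   histogram count matrix).
#' @export
clinical_summary <- function(clinical, assignment,
                             age_breaks = seq(0, 110, by = 10)) {
  merged <- merge(clinical, assignment[, c("sample_id", "subtype")],
                  by = "sample_id")
  if (nrow(merged) == 0) {
    stop("no overlap between clinical table and subtype assignment")
  }
  labs <- sort(unique(merged$subtype))
  out <- list()
  for (field in c("sex", "country")) {
    if (!field %in% names(merged)) next
    val <- merged[[field]]
    ok <- !is.na(val) & val != ""
    tab <- table(factor(merged$subtype[ok], levels = labs), val[ok])
    denom <- rowSums(tab)
    pct <- sweep(tab, 1, pmax(denom, 1), "/") * 100
    out[[field]] <- list(percent = as.matrix(pct),
                         denominator = as.integer(denom),
                         n_missing = sum(!ok))
  }
  if ("age" %in% names(merged)) {
    age <- suppressWarnings(as.numeric(merged$age))
    ok <- !is.na(age)
    summ <- do.call(rbind, lapply(labs, function(s) {
      a <- age[ok & merged$subtype == s]
      data.frame(subtype = s, n = length(a),
                 mean = if (length(a)) mean(a) else NA_real_,
                 median = if (length(a)) stats::median(a) else NA_real_,
                 sd = if (length(a) > 1) stats::sd(a) else NA_real_)
    }))
    hist_counts <- vapply(labs, function(s) {
      a <- age[ok & merged$subtype == s]
      a <- pmin(pmax(a, min(age_breaks)), max(age_breaks))
      as.integer(table(cut(a, age_breaks, include.lowest = TRUE)))
    }, integer(length(age_breaks) - 1))
    rownames(hist_counts) <- levels(cut(age_breaks[-1] - 1, age_breaks,
                                        include.lowest = TRUE))
    out$age <- list(summary = summ, histogram = hist_counts,
                    n_missing = sum(!ok))
  }
  out
}
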