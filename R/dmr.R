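# Two-group differential methylation testing per probe: binomial logistic
# regression on per-sample (methylated, unmethylated) totals with a single
# group indicator, likelihood-ratio p-values against the intercept-only
# model (chi-square, 1 df), Benjamini-Hochberg correction, and the dual
# significance rule (q below alpha AND absolute difference of at least
# `min_delta` percentage points).

# Core per-probe fit. Complete separation (one group at exactly 0% or 100%
# in all of its samples) is handled with a Haldane 0.5 pseudo-count added to
# both counts of every sample, refit, and flagged.
fit_binomial_lrt <- function(m, u, grp) {
  sep <- FALSE
  for (lev in levels(grp)) {
    i <- grp == lev
    if (all(m[i] == 0) || all(u[i] == 0)) sep <- TRUE
  }
  if (sep) {
    m <- m + 0.5
    u <- u + 0.5
  }
  fit <- suppressWarnings(stats::glm(cbind(m, u) ~ grp,
                                     family = stats::binomial()))
  dev <- fit$null.deviance - fit$deviance
  list(pvalue = stats::pchisq(max(dev, 0), df = 1, lower.tail = FALSE),
       deviance = dev, separation = sep)
}

#' Per-probe two-group differential methylation test
#'
#' For every probe, fits a binomial GLM with logit link on the per-sample
#' pooled (methylated, unmethylated) totals with a single group indicator
#' and computes the likelihood-ratio p-value against the intercept-only
#' model. The methylation difference `delta_pp` is the difference of group
#' means of the per-sample probe percentages (`group B - group A`, so
#' callers comparing knockout vs wild type pass WT as A and KO as B).
#' Samples with zero probe coverage are excluded from both fit and means.
#'
#' @param pset A filtered `probe_set`.
#' @param samples_a,samples_b Sample ids of the two groups (>= 2 each
#'   recommended; 1 is allowed and yields the pooled 2x2 contrast).
#' @param comparison Optional label stored in the result.
#' @return Data frame with one row per probe: coordinates, `mean_a`,
#'   `mean_b`, `delta_pp`, `pvalue`, `separation`.
#' @export
dmr_test <- function(pset, samples_a, samples_b, comparison = "B_vs_A") {
  stopifnot(inherits(pset, "probe_set"),
            all(c(samples_a, samples_b) %in% pset$samples),
            length(samples_a) >= 1, length(samples_b) >= 1)
  samp <- c(samples_a, samples_b)
  grp_all <- factor(rep(c("A", "B"), c(length(samples_a), length(samples_b))),
                    levels = c("A", "B"))
  M <- pset$meth[, samp, drop = FALSE]
  C <- pset$cov[, samp, drop = FALSE]
  P <- pset$pct[, samp, drop = FALSE]
  n <- nrow(pset$probes)
  pval <- delta <- ma <- mb <- rep(NA_real_, n)
  sepf <- rep(FALSE, n)
  for (i in seq_len(n)) {
    use <- C[i, ] > 0
    g <- grp_all[use]
    if (length(unique(g)) < 2) next
    m <- M[i, use]
    u <- C[i, use] - m
    fit <- fit_binomial_lrt(m, u, droplevels(g))
    pval[i] <- fit$pvalue
    sepf[i] <- fit$separation
    ma[i] <- mean(P[i, use][g == "A"])
    mb[i] <- mean(P[i, use][g == "B"])
    delta[i] <- mb[i] - ma[i]
  }
  out <- data.frame(probe_id = pset$probes$probe_id,
                    chrom = pset$probes$chrom,
                    start = pset$probes$start,
                    end = pset$probes$end,
                    mean_a = ma, mean_b = mb, delta_pp = delta,
                    pvalue = pval, separation = sepf,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  out
}

#' Call differentially methylated regions
#'
#' Applies Benjamini-Hochberg correction over all tested probes of one
#' comparison and flags a probe as a significant DMR when its corrected
#' q-value (or raw p-value, with `correction = "raw_p"`) is below `alpha`
#' and its absolute methylation difference is at least `min_delta`
#' percentage points. Direction is `hyper` for positive `delta_pp`
#' (higher in group B), `hypo` otherwise.
#'
#' @param tests Result of [dmr_test()].
#' @param alpha Significance threshold (default 0.05).
#' @param min_delta Minimum absolute methylation difference in percentage
#'   points (default 10).
#' @param correction `"BH_q"` (default) or `"raw_p"`.
#' @return The test table with added `qvalue`, `direction`, `significant`
#'   columns, class `dmr_calls`; summary counts are available through
#'   [dmr_counts()].
#' @export
call_dmrs <- function(tests, alpha = 0.05, min_delta = 10,
                      correction = c("BH_q", "raw_p")) {
  correction <- match.arg(correction)
  if (nrow(tests) == 0) stop("no tested probes to call DMRs on", call. = FALSE)
  out <- tests
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  crit <- if (correction == "BH_q") out$qvalue else out$pvalue
  out$direction <- ifelse(out$delta_pp > 0, "hyper", "hypo")
  out$significant <- !is.na(crit) & crit < alpha &
    abs(out$delta_pp) >= min_delta
  attr(out, "comparison") <- attr(tests, "comparison")
  attr(out, "alpha") <- alpha
  attr(out, "min_delta") <- min_delta
  attr(out, "correction") <- correction
  class(out) <- c("dmr_calls", "data.frame")
  out
}

#' Summary counts of a DMR call set
#'
#' @param calls A `dmr_calls` table.
#' @return Named integer vector `c(hyper = ..., hypo = ...)` over
#'   significant probes.
#' @export
dmr_counts <- function(calls) {
  sig <- calls[calls$significant, , drop = FALSE]
  c(hyper = sum(sig$direction == "hyper"),
    hypo = sum(sig$direction == "hypo"))
}

#' @export
print.dmr_calls <- function(x, ...) {
  n <- dmr_counts(x)
  cat(sprintf("dmr_calls [%s]: %d probes tested, %d hyper / %d hypo DMRs (alpha=%g, min |delta|=%g pp, %s)\n",
              attr(x, "comparison") %||% "?", nrow(x), n["hyper"], n["hypo"],
              attr(x, "alpha"), attr(x, "min_delta"), attr(x, "correction")))
  invisible(x)
}
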