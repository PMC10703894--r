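# Differential-expression signature ranking and preranked enrichment
# scores: the signed -log10(p) ranking metric, top-N signature extraction,
# and the classic weighted Kolmogorov-Smirnov running-sum enrichment score
# with a gene-label permutation null.

#' Signed significance ranking metric
#'
#' `sign(log2fc) * -log10(p)`, with the p-value floored at 1e-300 so the
#' metric stays finite; `sign(0) = 0`. Non-positive p-values are floored
#' with a warning.
#'
#' @param log2fc Log2 fold changes.
#' @param pvalue P-values in (0, 1].
#' @return Numeric metric vector.
#' @export
rank_metric <- function(log2fc, pvalue) {
  if (any(pvalue <= 0, na.rm = TRUE))
    warning("non-positive p-value(s) floored at 1e-300", call. = FALSE)
  p <- pmax(pvalue, 1e-300)
  sign(log2fc) * (-log10(p))
}

#' Rank genes by the signed significance metric
#'
#' Orders a DE table by descending metric with deterministic tie-breaking
#' (ascending gene id).
#'
#' @param de_table Data frame with `gene_id`, `log2fc`, `pvalue`.
#' @return Data frame `gene_id`, `metric`, class `ranked_genes`.
#' @export
rank_genes <- function(de_table) {
  m <- rank_metric(de_table$log2fc, de_table$pvalue)
  out <- data.frame(gene_id = de_table$gene_id, metric = m,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

#' Extract a top-N signature from a DE table
#'
#' Filters genes by fold-change sign, sorts by ascending p-value (ties by
#' larger `|log2fc|` first, then gene id) and takes the first `n`.
#'
#' @param de_table Data frame with `gene_id`, `log2fc`, `pvalue`.
#' @param n Signature size (default 100).
#' @param direction `"up"` (`log2fc > 0`) or `"down"` (`log2fc < 0`).
#' @return Character vector of gene ids (all qualifying genes, with a
#'   warning, when fewer than `n`).
#' @export
top_signature <- function(de_table, n = 100L, direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "up") de_table$log2fc > 0 else de_table$log2fc < 0
  sub <- de_table[keep & !is.na(keep), , drop = FALSE]
  sub <- sub[order(sub$pvalue, -abs(sub$log2fc), sub$gene_id), , drop = FALSE]
  if (nrow(sub) < n)
    warning("only ", nrow(sub), " ", direction, "-regulated genes available",
            " (requested ", n, ")", call. = FALSE)
  utils::head(sub$gene_id, n)
}

# running-sum ES over a 0/1 hit vector aligned with the ranked metrics;
# extremum by absolute value, first index on ties
es_from_hits <- function(metric, hit, weight_exponent = 1) {
  N <- length(metric)
  nh <- sum(hit)
  if (nh == 0) stop("gene set is disjoint from the ranked list", call. = FALSE)
  if (nh == N) return(list(es = 1, at = N, running = rep(1, N)))
  w <- abs(metric)^weight_exponent
  inc <- ifelse(hit, w, 0)
  denom <- sum(inc)
  if (denom == 0) {  # all-zero hit metrics: fall back to equal hit weights
    inc[hit] <- 1
    denom <- nh
  }
  running <- cumsum(inc / denom - (!hit) / (N - nh))
  at <- which.max(abs(running))
  list(es = running[at], at = at, running = running)
}

#' Preranked enrichment score with permutation p-value
#'
#' Classic weighted Kolmogorov-Smirnov running sum over the ranked list:
#' genes in the set increment the sum by `|metric|^weight_exponent`
#' (normalised by the set total), others decrement by `1/(N - |S|)`; the
#' enrichment score (ES) is the extremum of largest absolute value. The
#' null is formed by resampling size-matched gene-label sets; the
#' normalised score (NES) divides ES by the mean |null ES| of matching
#' sign, and the permutation p-value is the add-one-smoothed fraction of
#' matching-sign null scores at least as extreme.
#'
#' @param ranked A `ranked_genes` table from [rank_genes()].
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Hit weight exponent (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return List with `es`, `nes`, `pvalue`, `n_hits`, `leading_edge`
#'   (gene ids up to the extremum for positive ES, from it for negative),
#'   and `null_es`.
#' @export
preranked_es <- function(ranked, gene_set, weight_exponent = 1,
                         n_perm = 1000L, seed = NULL) {
  hit <- ranked$gene_id %in% gene_set
  res <- es_from_hits(ranked$metric, hit, weight_exponent)
  es <- res$es
  leading <- if (es >= 0) {
    ranked$gene_id[seq_len(res$at)][hit[seq_len(res$at)]]
  } else {
    idx <- res$at:length(hit)
    ranked$gene_id[idx][hit[idx]]
  }
  if (!is.null(seed)) set.seed(seed)
  N <- length(hit)
  nh <- sum(hit)
  null_es <- vapply(seq_len(n_perm), function(b) {
    h <- logical(N)
    h[sample.int(N, nh)] <- TRUE
    es_from_hits(ranked$metric, h, weight_exponent)$es
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  pval <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, pvalue = pval, n_hits = nh,
       leading_edge = leading, null_es = null_es)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param path GMT path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields", call. = FALSE)
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
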