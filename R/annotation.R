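# Regulatory annotation: histone-mark based enhancer classification,
# lineage-exclusive probe assignment, per-element DMR overlap fractions,
# and gene proximity linkage. Probe-element overlap requires >= 1 bp.

#' Classify enhancers from histone-mark peaks of one cell state
#'
#' An H3K27ac peak is called an enhancer when it does not overlap any known
#' promoter element and its H3K4me1 signal dominates H3K4me3. In
#' `"presence"` mode (default) that means: overlaps at least one H3K4me1
#' peak and no H3K4me3 peak. In `"score_ratio"` mode the summed `score` of
#' overlapping H3K4me1 peaks (plus `eps`) divided by the summed H3K4me3
#' score (plus `eps`) must exceed `ratio_threshold`.
#'
#' @param h3k27ac,h3k4me1,h3k4me3,promoters Interval data frames
#'   (0-based half-open) for one cell state.
#' @param mode `"presence"` or `"score_ratio"`.
#' @param ratio_threshold Ratio cut-off for `"score_ratio"` mode (default 1).
#' @param eps Guard against division by zero (default 1e-9).
#' @return The `h3k27ac` table with added columns `me1_evidence`,
#'   `me3_evidence` (counts or summed scores), `promoter_overlap`, and the
#'   logical `enhancer` call.
#' @export
classify_enhancers <- function(h3k27ac, h3k4me1, h3k4me3, promoters,
                               mode = c("presence", "score_ratio"),
                               ratio_threshold = 1, eps = 1e-9) {
  mode <- match.arg(mode)
  out <- h3k27ac
  if (nrow(out) == 0) {
    out$me1_evidence <- numeric(); out$me3_evidence <- numeric()
    out$promoter_overlap <- logical(); out$enhancer <- logical()
    return(out)
  }
  gr <- as_gr0(out)
  count_or_score <- function(peaks, use_score) {
    if (nrow(peaks) == 0) return(numeric(nrow(out)))
    hits <- ov_find(gr, as_gr0(peaks))
    v <- numeric(nrow(out))
    if (use_score) {
      sc <- peaks$score[S4Vectors::subjectHits(hits)]
      if (any(is.na(sc)))
        stop("score_ratio mode requires score values on histone peaks",
             call. = FALSE)
      tab <- tapply(sc, S4Vectors::queryHits(hits), sum)
    } else {
      tab <- table(S4Vectors::queryHits(hits))
    }
    v[as.integer(names(tab))] <- as.numeric(tab)
    v
  }
  use_score <- mode == "score_ratio"
  out$me1_evidence <- count_or_score(h3k4me1, use_score)
  out$me3_evidence <- count_or_score(h3k4me3, use_score)
  out$promoter_overlap <- if (nrow(promoters) == 0) {
    rep(FALSE, nrow(out))
  } else {
    ov_count(gr, as_gr0(promoters)) > 0
  }
  out$enhancer <- if (use_score) {
    !out$promoter_overlap &
      (out$me1_evidence + eps) / (out$me3_evidence + eps) > ratio_threshold
  } else {
    !out$promoter_overlap & out$me1_evidence > 0 & out$me3_evidence == 0
  }
  out
}

#' Assign lineage-exclusive enhancer state labels to probes
#'
#' A probe overlapping enhancers of exactly one cell state receives that
#' state's label; probes overlapping enhancers of two or more states are
#' labelled `"multi"` (excluded from lineage-specific analyses) and probes
#' overlapping none are `"none"`.
#'
#' @param pset A `probe_set` (or probe window data frame).
#' @param enhancers_by_state Named list (state -> interval data frame of
#'   classified enhancers).
#' @return Data frame `probe_id`, `state`.
#' @export
assign_state_specific_probes <- function(pset, enhancers_by_state) {
  probes <- if (inherits(pset, "probe_set")) pset$probes else pset
  gr <- as_gr0(probes)
  hit <- vapply(enhancers_by_state, function(enh) {
    if (nrow(enh) == 0) return(rep(FALSE, nrow(probes)))
    ov_count(gr, as_gr0(enh)) > 0
  }, logical(nrow(probes)))
  if (nrow(probes) == 1) hit <- matrix(hit, nrow = 1,
                                       dimnames = list(NULL, names(enhancers_by_state)))
  nstate <- rowSums(hit)
  state <- rep("none", nrow(probes))
  one <- nstate == 1
  state[one] <- colnames(hit)[apply(hit[one, , drop = FALSE], 1, which)]
  state[nstate >= 2] <- "multi"
  data.frame(probe_id = probes$probe_id, state = state,
             stringsAsFactors = FALSE)
}

#' Fraction of element-overlapping probes that are DMRs
#'
#' For each named genomic element class, the denominator is the set of
#' tested probes overlapping the element by at least 1 bp; the numerators
#' are the significant hyper-/hypomethylated DMRs among them. Elements with
#' no overlapping tested probe are reported as `NA` (undefined), not 0.
#'
#' @param calls A `dmr_calls` table.
#' @param element_sets Named list (element class -> interval data frame).
#' @return Data frame `element`, `n_probes`, `n_hyper`, `n_hypo`,
#'   `pct_hyper`, `pct_hypo`.
#' @export
element_dmr_fractions <- function(calls, element_sets) {
  gr <- as_gr0(calls)
  rows <- lapply(names(element_sets), function(nm) {
    el <- element_sets[[nm]]
    ov <- if (nrow(el) == 0) rep(FALSE, nrow(calls)) else
      ov_count(gr, as_gr0(el)) > 0
    n <- sum(ov)
    sub <- calls[ov, , drop = FALSE]
    nh <- sum(sub$significant & sub$direction == "hyper")
    nl <- sum(sub$significant & sub$direction == "hypo")
    data.frame(element = nm, n_probes = n, n_hyper = nh, n_hypo = nl,
               pct_hyper = if (n > 0) 100 * nh / n else NA_real_,
               pct_hypo = if (n > 0) 100 * nl / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Link intervals to genes within a distance
#'
#' Distance is 0 when the interval overlaps the gene body, otherwise the
#' gap between the closest ends. All genes at distance `<= max_distance_bp`
#' are returned, sorted by distance then gene id within each interval.
#'
#' @param intervals Interval data frame; `name` (if present) identifies the
#'   interval in the output.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end` (and
#'   optionally `strand`).
#' @param max_distance_bp Maximum gap in bp (default 2000).
#' @return Data frame `interval`, `gene_id`, `distance`.
#' @export
link_genes <- function(intervals, genes, max_distance_bp = 2000) {
  iname <- if (!is.null(intervals$name) && !all(is.na(intervals$name)))
    intervals$name else sprintf("%s:%d-%d", intervals$chrom,
                                intervals$start, intervals$end)
  empty <- data.frame(interval = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (nrow(intervals) == 0 || nrow(genes) == 0) return(empty)
  gri <- as_gr0(intervals)
  grg <- as_gr0(genes)
  hits <- ov_find(gri, grg, maxgap = max_distance_bp)
  if (length(hits) == 0) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- ov_distance(gri[qh], grg[sh])
  keep <- d <= max_distance_bp
  out <- data.frame(interval = iname[qh][keep],
                    gene_id = genes$gene_id[sh][keep],
                    distance = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(match(out$interval, iname), out$distance, out$gene_id), ,
      drop = FALSE]
}

#' Classify an interval's relation to a gene
#'
#' `promoter` when the interval overlaps the gene's promoter window
#' (TSS - `promoter_upstream` .. TSS + `promoter_downstream`, strand
#' aware); `intragenic` when it overlaps the gene body but not the
#' promoter; `distal` otherwise. Vectorised over matched rows of
#' `intervals` and `genes`.
#'
#' @param intervals Interval data frame.
#' @param genes Gene data frame (`chrom`, `start`, `end`, `strand`), one row
#'   per interval row (recycled if single).
#' @param promoter_upstream,promoter_downstream Promoter window relative to
#'   the TSS in bp (defaults 1000 and 500).
#' @return Character vector in `{promoter, intragenic, distal}`.
#' @export
classify_gene_relation <- function(intervals, genes,
                                   promoter_upstream = 1000,
                                   promoter_downstream = 500) {
  if (nrow(genes) == 1 && nrow(intervals) > 1)
    genes <- genes[rep(1, nrow(intervals)), , drop = FALSE]
  stopifnot(nrow(genes) == nrow(intervals))
  st <- genes$strand
  st[is.na(st) | !(st %in% c("+", "-"))] <- "+"
  tss <- ifelse(st == "+", genes$start, genes$end - 1L)
  prom_start <- ifelse(st == "+", tss - promoter_upstream,
                       tss - promoter_downstream + 1L)
  prom_end <- ifelse(st == "+", tss + promoter_downstream,
                     tss + promoter_upstream + 1L)
  prom_start <- pmax(prom_start, 0L)
  same_chrom <- as.character(intervals$chrom) == as.character(genes$chrom)
  ov <- function(s1, e1, s2, e2) same_chrom & s1 < e2 & s2 < e1
  in_prom <- ov(intervals$start, intervals$end, prom_start, prom_end)
  in_body <- ov(intervals$start, intervals$end, genes$start, genes$end)
  out <- rep("distal", nrow(intervals))
  out[in_body] <- "intragenic"
  out[in_prom] <- "promoter"
  out
}
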