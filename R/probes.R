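# Tiling of the genome into windows of exactly `window_cpgs` consecutive
# CpGs ("probes"), per-sample quantification by pooled counts, the
# per-comparison coverage filter, and group-level methylation summaries.

#' Tile CpG positions into fixed-size windowed probes
#'
#' Partitions the CpGs of each chromosome into consecutive, non-overlapping
#' windows of exactly `window_cpgs` CpGs. A trailing remainder of fewer than
#' `window_cpgs` CpGs is discarded, so every emitted probe holds the full
#' window. Probes never span chromosomes. The probe interval runs from the
#' first member CpG to the last member CpG plus 2 (covering its G),
#' 0-based half-open.
#'
#' @param cpg A `cpg_matrix` or a data frame with columns `chrom`, `pos`
#'   (sorted, unique within chromosome).
#' @param window_cpgs Number of CpGs per probe (default 50).
#' @return Data frame of probe windows: `probe_id`, `chrom`, `start`, `end`,
#'   `n_cpgs`, plus `first_idx`/`last_idx` row indices into the CpG table.
#' @export
tile_probes <- function(cpg, window_cpgs = 50L) {
  if (inherits(cpg, "cpg_matrix")) {
    chrom <- cpg$chrom; pos <- cpg$pos
  } else {
    chrom <- as.character(cpg$chrom); pos <- as.integer(cpg$pos)
  }
  window_cpgs <- as.integer(window_cpgs)
  stopifnot(window_cpgs >= 1L)
  if (is.unsorted(order(chrom, pos)))
    stop("CpG positions must be sorted by chromosome and position", call. = FALSE)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (anyDuplicated(p)) stop("duplicate CpG positions on ", ch, call. = FALSE)
    nwin <- length(p) %/% window_cpgs
    if (nwin == 0) next
    first <- (seq_len(nwin) - 1L) * window_cpgs + 1L
    last <- first + window_cpgs - 1L
    out[[ch]] <- data.frame(
      chrom = ch,
      start = p[first],
      end = p[last] + 2L,
      n_cpgs = window_cpgs,
      first_idx = idx[first],
      last_idx = idx[last],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    win <- data.frame(probe_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_cpgs = integer(),
                      first_idx = integer(), last_idx = integer(),
                      stringsAsFactors = FALSE)
    return(win)
  }
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  win <- cbind(probe_id = sprintf("%s:%d-%d", win$chrom, win$start, win$end),
               win, stringsAsFactors = FALSE)
  win
}

#' Quantify probes against multi-sample CpG counts
#'
#' Aggregates per-CpG methylated/total counts over each probe's member CpGs
#' for every sample (pooled counts, i.e. coverage-weighted), and records per
#' sample how many member CpGs have coverage of at least one read. The
#' probe methylation percentage is `100 * sum(meth) / sum(cov)`, undefined
#' (`NA`) when the probe has zero total coverage in that sample.
#'
#' @param windows Probe windows from [tile_probes()] (tiled on `cpg`).
#' @param cpg The `cpg_matrix` the windows index into.
#' @return An object of class `probe_set`: list with `probes` (the window
#'   table), matrices `meth`, `cov`, `covered_cpgs`, `pct` (probe x sample),
#'   and `samples`.
#' @export
quantify_probes <- function(windows, cpg) {
  stopifnot(inherits(cpg, "cpg_matrix"))
  n <- nrow(windows)
  grp <- rep(NA_integer_, length(cpg$pos))
  for (i in seq_len(n)) grp[windows$first_idx[i]:windows$last_idx[i]] <- i
  keep <- !is.na(grp)
  g <- grp[keep]
  agg <- function(m) {
    out <- rowsum(m[keep, , drop = FALSE], group = g, reorder = TRUE)
    out[match(seq_len(n), as.integer(rownames(out))), , drop = FALSE]
  }
  meth <- agg(cpg$meth)
  cov <- agg(cpg$cov)
  covered <- agg((cpg$cov > 0) + 0L)
  pct <- 100 * meth / cov  # NaN when cov == 0
  pct[cov == 0] <- NA_real_
  dimnames(meth) <- dimnames(cov) <- dimnames(covered) <- dimnames(pct) <-
    list(windows$probe_id, cpg$samples)
  structure(list(probes = windows, meth = meth, cov = cov,
                 covered_cpgs = covered, pct = pct, samples = cpg$samples),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d probes x %d samples (%d CpGs per probe)\n",
              nrow(x$probes), length(x$samples),
              if (nrow(x$probes)) x$probes$n_cpgs[1] else 0L))
  invisible(x)
}

subset_probe_set <- function(pset, idx) {
  structure(list(probes = pset$probes[idx, , drop = FALSE],
                 meth = pset$meth[idx, , drop = FALSE],
                 cov = pset$cov[idx, , drop = FALSE],
                 covered_cpgs = pset$covered_cpgs[idx, , drop = FALSE],
                 pct = pset$pct[idx, , drop = FALSE],
                 samples = pset$samples),
            class = "probe_set")
}

#' Per-comparison probe coverage filter
#'
#' A probe passes when it has at least `min_covered_cpgs` CpGs with at least
#' one read in *every* sample of the comparison. Probes are meant to be
#' re-filtered for each two-group comparison over that comparison's samples.
#'
#' @param pset A `probe_set`.
#' @param samples Samples of the comparison (default: all samples).
#' @param min_covered_cpgs Minimum covered CpGs per sample (default 10).
#' @return The filtered `probe_set`, with attribute `"pass"` holding the
#'   logical vector over the input probes.
#' @export
apply_coverage_filter <- function(pset, samples = pset$samples,
                                  min_covered_cpgs = 10L) {
  stopifnot(inherits(pset, "probe_set"), all(samples %in% pset$samples))
  cc <- pset$covered_cpgs[, samples, drop = FALSE]
  pass <- rowSums(cc >= min_covered_cpgs) == length(samples)
  out <- subset_probe_set(pset, which(pass))
  attr(out, "pass") <- pass
  out
}

#' Probe methylation percentage for one sample
#'
#' Pooled-count percentage over the probe's CpGs:
#' `100 * sum(meth) / sum(meth + unmeth)`; `NA` when total coverage is zero.
#'
#' @param pset A `probe_set`.
#' @param sample Sample id.
#' @return Numeric vector over probes.
#' @export
probe_methylation <- function(pset, sample) {
  stopifnot(sample %in% pset$samples)
  pset$pct[, sample]
}

#' Group-level global methylation summary
#'
#' For each group, the per-probe group value is the unweighted mean of the
#' per-sample methylation percentages (samples with undefined probe
#' methylation excluded); the summary is the mean and standard error of
#' that value across probes.
#'
#' @param pset A (typically filtered) `probe_set`.
#' @param groups Named list mapping group label to sample ids.
#' @return Data frame with `group`, `n_probes`, `mean_pct`, `sem`.
#' @export
global_methylation_summary <- function(pset, groups) {
  if (nrow(pset$probes) == 0) stop("no probes to summarise", call. = FALSE)
  rows <- lapply(names(groups), function(g) {
    samp <- groups[[g]]
    stopifnot(all(samp %in% pset$samples))
    val <- rowMeans(pset$pct[, samp, drop = FALSE], na.rm = TRUE)
    val <- val[is.finite(val)]
    data.frame(group = g, n_probes = length(val), mean_pct = mean(val),
               sem = stats::sd(val) / sqrt(length(val)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
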