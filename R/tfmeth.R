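# Methylation scoring over transcription-factor ChIP binding sites: one
# probe per peak interval (pooled CpG counts within the peak), per-TF
# summaries referenced against the genome-wide average difference, and
# linkage of significantly hypermethylated sites to downregulated genes.

#' Build per-TF methylation probes over ChIP peak intervals
#'
#' Creates one probe per peak interval, quantified by pooled counts of the
#' CpGs falling inside the peak, per sample. A probe is `covered` when it
#' has at least one covered CpG in every sample; peaks with no CpGs are
#' retained but permanently uncovered.
#'
#' @param tf_peaks Named list (TF -> interval data frame of ChIP peaks).
#' @param cpg A `cpg_matrix`.
#' @return Named list of per-TF objects: list with `peaks` (interval table),
#'   matrices `meth`, `cov`, `pct`, `covered_cpgs`, logical `covered`, and
#'   `samples`.
#' @export
build_tf_probes <- function(tf_peaks, cpg) {
  stopifnot(inherits(cpg, "cpg_matrix"), !is.null(names(tf_peaks)))
  cgr <- GenomicRanges::GRanges(cpg$chrom,
                                IRanges::IRanges(cpg$pos + 1L, cpg$pos + 2L))
  lapply(tf_peaks, function(peaks) {
    n <- nrow(peaks)
    s <- length(cpg$samples)
    meth <- cov <- covered <- matrix(0L, n, s,
                                     dimnames = list(peaks$name, cpg$samples))
    if (n > 0) {
      hits <- ov_find(as_gr0(peaks), cgr,
                                          type = "any")
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      meth <- rowsum_into(cpg$meth, qh, sh, n)
      cov <- rowsum_into(cpg$cov, qh, sh, n)
      covered <- rowsum_into((cpg$cov > 0) + 0L, qh, sh, n)
      dimnames(meth) <- dimnames(cov) <- dimnames(covered) <-
        list(peaks$name, cpg$samples)
    }
    pct <- 100 * meth / cov
    pct[cov == 0] <- NA_real_
    structure(list(peaks = peaks, meth = meth, cov = cov, pct = pct,
                   covered_cpgs = covered,
                   covered = rowSums(covered >= 1) == s,
                   samples = cpg$samples),
              class = "tf_probe_set")
  })
}

# sum rows of `mat` (CpG x sample) into `n` peak rows given overlap hits
rowsum_into <- function(mat, qh, sh, n) {
  out <- matrix(0L, n, ncol(mat))
  if (length(qh)) {
    agg <- rowsum(mat[sh, , drop = FALSE], group = qh, reorder = TRUE)
    out[as.integer(rownames(agg)), ] <- agg
  }
  out
}

#' Per-TF binding-site methylation difference summary
#'
#' For each covered peak probe, computes the methylation difference
#' `delta_pp` between the group means of per-sample percentages (KO - WT)
#' together with a likelihood-ratio p-value (same model as [dmr_test()]),
#' and summarises the TF as: mean difference, excess over the genome-wide
#' average difference, and the percentage of sites with strictly higher
#' methylation in KO. TFs with `n_probes_covered <= min_probes` are marked
#' not included.
#'
#' @param tfp One element of [build_tf_probes()] output.
#' @param samples_wt,samples_ko Sample ids of the two groups.
#' @param genome_mean_delta Genome-wide reference: mean `delta_pp` over all
#'   tested 50-CpG probes of the same comparison.
#' @param tf_name TF label for the summary row.
#' @param min_probes Coverage-sufficiency threshold (default 100; a TF is
#'   included only when strictly more than `min_probes` covered probes).
#' @return List with `summary` (one-row data frame) and `sites` (per-probe
#'   MA records: `name`, coordinates, `mean_wt`, `mean_ko`, `mean_meth`,
#'   `delta_pp`, `pvalue`).
#' @export
tf_meth_difference <- function(tfp, samples_wt, samples_ko,
                               genome_mean_delta, tf_name = "TF",
                               min_probes = 100L) {
  stopifnot(inherits(tfp, "tf_probe_set"))
  idx <- which(tfp$covered)
  samp <- c(samples_wt, samples_ko)
  grp <- factor(rep(c("A", "B"), c(length(samples_wt), length(samples_ko))),
                levels = c("A", "B"))
  sites <- NULL
  if (length(idx)) {
    mwt <- rowMeans(tfp$pct[idx, samples_wt, drop = FALSE])
    mko <- rowMeans(tfp$pct[idx, samples_ko, drop = FALSE])
    pv <- vapply(idx, function(i) {
      m <- tfp$meth[i, samp]
      u <- tfp$cov[i, samp] - m
      fit_binomial_lrt(m, u, grp)$pvalue
    }, numeric(1))
    sites <- data.frame(name = tfp$peaks$name[idx],
                        chrom = tfp$peaks$chrom[idx],
                        start = tfp$peaks$start[idx],
                        end = tfp$peaks$end[idx],
                        mean_wt = mwt, mean_ko = mko,
                        mean_meth = (mwt + mko) / 2,
                        delta_pp = mko - mwt,
                        pvalue = pv,
                        stringsAsFactors = FALSE)
  }
  n_cov <- length(idx)
  summary <- data.frame(
    tf_name = tf_name,
    n_probes_covered = n_cov,
    mean_delta_pp = if (n_cov) mean(sites$delta_pp) else NA_real_,
    genome_mean_delta_pp = genome_mean_delta,
    excess_delta_pp = if (n_cov) mean(sites$delta_pp) - genome_mean_delta
      else NA_real_,
    pct_sites_higher_in_KO = if (n_cov) 100 * mean(sites$delta_pp > 0)
      else NA_real_,
    included = n_cov > min_probes,
    stringsAsFactors = FALSE
  )
  list(summary = summary, sites = sites)
}

#' Run the TF methylation analysis over all TFs of one comparison
#'
#' @param tf_probes Output of [build_tf_probes()].
#' @param samples_wt,samples_ko Group sample ids.
#' @param genome_mean_delta Shared genome-wide reference difference.
#' @param min_probes Coverage-sufficiency threshold (default 100).
#' @return List with `summary` (one row per TF) and `sites` (named list of
#'   per-TF site tables). Excluded TFs stay in the summary with
#'   `included = FALSE`.
#' @export
tf_meth_analysis <- function(tf_probes, samples_wt, samples_ko,
                             genome_mean_delta, min_probes = 100L) {
  res <- lapply(names(tf_probes), function(tf) {
    tf_meth_difference(tf_probes[[tf]], samples_wt, samples_ko,
                       genome_mean_delta, tf_name = tf,
                       min_probes = min_probes)
  })
  summary <- do.call(rbind, lapply(res, `[[`, "summary"))
  excl <- summary$tf_name[!summary$included]
  if (length(excl))
    message("TFs excluded for insufficient covered probes (<= ", min_probes,
            "): ", paste(excl, collapse = ", "))
  sites <- lapply(res, `[[`, "sites")
  names(sites) <- summary$tf_name
  list(summary = summary, sites = sites)
}

#' Top-k TFs by mean binding-site methylation increase
#'
#' Ranks included TFs by descending `mean_delta_pp`; ties are broken
#' lexicographically by TF name.
#'
#' @param summary TF summary table from [tf_meth_analysis()].
#' @param k Number of TFs to return (default 10).
#' @return The top rows of the summary, reordered.
#' @export
rank_tfs <- function(summary, k = 10L) {
  inc <- summary[summary$included, , drop = FALSE]
  inc <- inc[order(-inc$mean_delta_pp, inc$tf_name), , drop = FALSE]
  if (nrow(inc) < k) {
    warning("only ", nrow(inc), " included TFs available (k = ", k, ")",
            call. = FALSE)
    k <- nrow(inc)
  }
  utils::head(inc, k)
}

#' Link hypermethylated TF sites to downregulated genes
#'
#' Intersects the `top_n` most significantly downregulated genes
#' (`log2fc < 0`, ascending p-value, ties by gene id) with the genes lying
#' within `max_distance` bp of any significantly hypermethylated site
#' (`delta_pp > 0` and raw `pvalue < alpha`).
#'
#' @param sites Site table(s) from [tf_meth_difference()] (rbind across TFs
#'   as desired); must carry `delta_pp` and `pvalue`.
#' @param de_table DE table with `gene_id`, `log2fc`, `pvalue`.
#' @param genes Gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param top_n Number of top downregulated genes (default 100).
#' @param max_distance Linkage distance in bp (default 2000).
#' @param alpha Site significance threshold on the raw p-value (default
#'   0.05).
#' @return Data frame of linked genes with DE statistics, the number of
#'   supporting sites and the nearest supporting site (`site`, `distance`,
#'   `site_delta_pp`, `site_pvalue`).
#' @export
link_downregulated_genes <- function(sites, de_table, genes, top_n = 100L,
                                     max_distance = 2000, alpha = 0.05) {
  down <- de_table[!is.na(de_table$log2fc) & de_table$log2fc < 0, ,
                   drop = FALSE]
  empty <- data.frame(gene_id = character(), log2fc = numeric(),
                      pvalue = numeric(), n_sites = integer(),
                      site = character(), distance = integer(),
                      site_delta_pp = numeric(), site_pvalue = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(down) == 0) {
    warning("DE table contains no downregulated genes", call. = FALSE)
    return(empty)
  }
  down <- down[order(down$pvalue, down$gene_id), , drop = FALSE]
  top <- utils::head(down, top_n)
  hyper <- sites[sites$delta_pp > 0 & sites$pvalue < alpha, , drop = FALSE]
  if (nrow(hyper) == 0) return(empty)
  links <- link_genes(hyper, genes, max_distance_bp = max_distance)
  links <- links[links$gene_id %in% top$gene_id, , drop = FALSE]
  if (nrow(links) == 0) return(empty)
  rows <- lapply(split(links, links$gene_id), function(lg) {
    lg <- lg[order(lg$distance, lg$interval), , drop = FALSE]
    i <- match(lg$interval[1], hyper$name)
    data.frame(gene_id = lg$gene_id[1], n_sites = nrow(lg),
               site = lg$interval[1], distance = lg$distance[1],
               site_delta_pp = hyper$delta_pp[i],
               site_pvalue = hyper$pvalue[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(top[, c("gene_id", "log2fc", "pvalue")], out, by = "gene_id")
  out <- out[order(out$pvalue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MA plot of TF binding-site methylation
#'
#' Mean methylation of each covered site (x) against the KO - WT
#' difference (y), base graphics.
#'
#' @param sites Site table from [tf_meth_difference()].
#' @param main Plot title.
#' @export
plot_tf_ma <- function(sites, main = "") {
  plot(sites$mean_meth, sites$delta_pp, pch = 16, cex = 0.5,
       col = ifelse(sites$delta_pp > 0, "firebrick", "grey40"),
       xlab = "mean methylation (%)", ylab = "KO - WT (pp)", main = main)
  graphics::abline(h = 0, lty = 2)
}
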