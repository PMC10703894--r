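# End-to-end pipeline over the simulator's file outputs: read coverage ->
# tile/quantify -> filter & test per treatment arm -> classify enhancers
# and assign lineage-exclusive probes -> element DMR fractions -> TF
# binding-site methylation & downregulated-gene linkage -> motif
# enrichment -> DE ranking and preranked enrichment score. Every result
# table is written as a deterministic TSV under `<outdir>/results`.

#' Run the full methylome analysis pipeline on a simulated study
#'
#' Simulates a complete study with [simulate_methylome()], reads every
#' input back through the file readers (so the run exercises the exact
#' formats a real study would arrive in), and executes the analysis
#' stages. The KO-vs-WT contrast is tested independently within each
#' treatment arm; probes are re-filtered per arm over that arm's samples.
#'
#' @param outdir Working directory: inputs land in `<outdir>/inputs`,
#'   result TSVs in `<outdir>/results`.
#' @param config A `sim_config` (default `sim_config()`).
#' @param window_cpgs,min_covered_cpgs Probe tiling and filter parameters
#'   (defaults 50 and 10).
#' @param alpha,min_delta,correction DMR significance rule (defaults 0.05,
#'   10 pp, BH q).
#' @param min_tf_probes TF coverage-sufficiency threshold (default 100).
#' @param top_n_genes Top downregulated genes for the linkage step
#'   (default 100).
#' @param link_distance Gene linkage distance in bp (default 2000).
#' @param pwms PWM list for motif enrichment (default [default_pwms()]
#'   using the configured planted consensus).
#' @param n_perm Permutations for the enrichment score (default 1000).
#' @return List with all intermediate and final objects: `sim`, `cpg`,
#'   `pset`, per-arm `dmr`, `enhancers`, `probe_states`,
#'   `element_fractions`, `tf`, `linked_genes`, `motif`, `signature`,
#'   `global_meth`, and `result_files`.
#' @export
run_methylome_pipeline <- function(outdir, config = sim_config(),
                                   window_cpgs = config$window_cpgs,
                                   min_covered_cpgs = 10L,
                                   alpha = 0.05, min_delta = 10,
                                   correction = "BH_q",
                                   min_tf_probes = 100L,
                                   top_n_genes = 100L,
                                   link_distance = 2000,
                                   pwms = default_pwms(config$motif_consensus),
                                   n_perm = 1000L) {
  sim <- simulate_methylome(config, file.path(outdir, "inputs"))
  resdir <- file.path(outdir, "results")
  dir.create(resdir, recursive = TRUE, showWarnings = FALSE)
  samples <- sim$samples

  # read inputs back from disk
  covs <- lapply(samples$sample_id, function(s)
    read_coverage(sim$paths$coverage[[s]], sample_id = s))
  names(covs) <- samples$sample_id
  cpg <- merge_coverage(covs)
  genome <- read_fasta(sim$paths$genome)
  de_table <- read_de_table(sim$paths$de_table)
  genes <- utils::read.table(sim$paths$genes, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  promoters <- read_bed(sim$paths$promoters)
  cpg_islands <- read_bed(sim$paths$cpg_islands)
  states <- config$states
  histone <- lapply(stats::setNames(states, states), function(st) {
    lapply(c(H3K27ac = "H3K27ac", H3K4me1 = "H3K4me1",
             H3K4me3 = "H3K4me3"), function(mark)
      read_bed(sim$paths$histone[[paste(mark, st)]]))
  })
  tf_peaks <- lapply(sim$paths$tf, read_bed)

  # probes
  windows <- tile_probes(cpg, window_cpgs = window_cpgs)
  pset <- quantify_probes(windows, cpg)
  arms <- unique(samples$treatment)
  arm_samples <- lapply(stats::setNames(arms, arms), function(a) {
    list(wt = samples$sample_id[samples$genotype == "WT" &
                                  samples$treatment == a],
         ko = samples$sample_id[samples$genotype == "KO" &
                                  samples$treatment == a])
  })
  group_list <- stats::setNames(
    lapply(seq_len(nrow(config$groups)), function(i)
      samples$sample_id[samples$genotype == config$groups$genotype[i] &
                          samples$treatment == config$groups$treatment[i]]),
    paste(config$groups$genotype, config$groups$treatment, sep = "_"))

  # enhancer classification + state-exclusive probe labels
  enhancers <- lapply(histone, function(h)
    classify_enhancers(h$H3K27ac, h$H3K4me1, h$H3K4me3, promoters))
  enhancer_sets <- lapply(enhancers, function(e)
    e[e$enhancer, , drop = FALSE])
  probe_states <- assign_state_specific_probes(pset, enhancer_sets)
  write_results_tsv(probe_states, file.path(resdir, "probe_states.tsv"))

  tf_probes <- build_tf_probes(tf_peaks, cpg)

  dmr <- list(); element_fractions <- list(); tf <- list()
  linked_genes <- list(); motif <- list(); global_meth <- list()
  for (a in arms) {
    gs <- arm_samples[[a]]
    filtered <- apply_coverage_filter(pset, samples = c(gs$wt, gs$ko),
                                      min_covered_cpgs = min_covered_cpgs)
    tests <- dmr_test(filtered, gs$wt, gs$ko,
                      comparison = paste0("KO_vs_WT_", a))
    calls <- call_dmrs(tests, alpha = alpha, min_delta = min_delta,
                       correction = correction)
    dmr[[a]] <- calls
    write_results_tsv(as.data.frame(calls),
                      file.path(resdir, sprintf("dmr_KO_vs_WT_%s.tsv", a)))

    element_sets <- c(
      stats::setNames(enhancer_sets, paste0("enhancer_", names(enhancer_sets))),
      list(promoters = promoters, cpg_islands = cpg_islands,
           gene_bodies = genes))
    element_fractions[[a]] <- element_dmr_fractions(calls, element_sets)
    write_results_tsv(element_fractions[[a]],
                      file.path(resdir,
                                sprintf("element_dmr_fractions_%s.tsv", a)))

    genome_mean_delta <- mean(calls$delta_pp, na.rm = TRUE)
    tfa <- tf_meth_analysis(tf_probes, gs$wt, gs$ko, genome_mean_delta,
                            min_probes = min_tf_probes)
    tf[[a]] <- tfa
    write_results_tsv(tfa$summary,
                      file.path(resdir, sprintf("tf_summary_%s.tsv", a)))
    all_sites <- do.call(rbind, tfa$sites[tfa$summary$tf_name[
      tfa$summary$included]])
    if (!is.null(all_sites)) {
      write_results_tsv(all_sites,
                        file.path(resdir, sprintf("tf_sites_%s.tsv", a)))
      linked_genes[[a]] <- link_downregulated_genes(
        all_sites, de_table, genes, top_n = top_n_genes,
        max_distance = link_distance, alpha = alpha)
      write_results_tsv(linked_genes[[a]],
                        file.path(resdir, sprintf("linked_genes_%s.tsv", a)))
    }
    motif[[a]] <- enrich_dmrs(calls, genome, pwms, direction = "hyper")
    write_results_tsv(motif[[a]],
                      file.path(resdir, sprintf("motif_enrichment_%s.tsv", a)))
  }
  global_meth <- global_methylation_summary(
    apply_coverage_filter(pset, min_covered_cpgs = min_covered_cpgs),
    group_list)
  write_results_tsv(global_meth, file.path(resdir, "global_methylation.tsv"))

  # DE signature: rank genes, then score the methylation-linked gene set
  ranked <- rank_genes(de_table)
  write_results_tsv(ranked, file.path(resdir, "ranked_genes.rnk.tsv"))
  sig_down <- top_signature(de_table, n = top_n_genes, direction = "down")
  link_set <- unique(unlist(lapply(linked_genes, function(x) x$gene_id)))
  signature <- NULL
  if (length(link_set)) {
    es <- preranked_es(ranked, link_set, n_perm = n_perm,
                       seed = config$seed + 3L)
    signature <- data.frame(set = "methylation_linked_downregulated",
                            size = length(link_set), es = es$es,
                            nes = es$nes, pvalue = es$pvalue,
                            leading_edge = paste(es$leading_edge,
                                                 collapse = ","),
                            stringsAsFactors = FALSE)
    write_results_tsv(signature, file.path(resdir, "signature_es.tsv"))
  }
  result_files <- list.files(resdir, full.names = TRUE)
  list(sim = sim, cpg = cpg, pset = pset, samples = samples,
       arm_samples = arm_samples, dmr = dmr, enhancers = enhancers,
       enhancer_sets = enhancer_sets, probe_states = probe_states,
       element_fractions = element_fractions, tf = tf,
       linked_genes = linked_genes, motif = motif, de_table = de_table,
       genes = genes, ranked = ranked, signature_down = sig_down,
       signature = signature, global_meth = global_meth,
       result_files = result_files)
}
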