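# The synthetic methylome generator: determinism, CpG extraction, planted
# feature geometry, parameter recovery, file validity.

test_that("identical seeds give byte-identical output sets", {
  cfg <- small_config(seed = 11)
  d1 <- file.path(tempdir(), "sim-det-1")
  d2 <- file.path(tempdir(), "sim-det-2")
  s1 <- simulate_methylome(cfg, d1)
  s2 <- simulate_methylome(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the CpG list is exactly the CG positions of the emitted FASTA", {
  sim <- small_sim()
  seqs <- read_fasta(sim$paths$genome)
  cpg_file <- read_coverage(sim$paths$coverage[[1]])
  for (ch in names(seqs)) {
    m <- gregexpr("CG", as.character(seqs[[ch]]), fixed = TRUE)[[1]]
    got <- if (m[1] == -1) integer() else as.integer(m) - 1L
    expect_equal(cpg_file$pos[cpg_file$chrom == ch], got)
  }
})

test_that("a genome too small for the requested features errors clearly", {
  expect_error(simulate_genome(sim_config(seed = 1, genome_length_bp = 5e4)),
               "too small")
})

test_that("enhancers never overlap each other (brute-force sweep)", {
  enh <- small_sim()$truth$enhancers
  for (i in seq_len(nrow(enh) - 1))
    for (j in (i + 1):nrow(enh)) {
      same <- enh$chrom[i] == enh$chrom[j]
      ov <- same && enh$start[i] < enh$end[j] && enh$start[j] < enh$end[i]
      expect_false(ov)
    }
})

test_that("planted motif instances sit at their recorded positions", {
  sim <- small_sim()
  seqs <- read_fasta(sim$paths$genome)
  mp <- sim$truth$motif_positions
  expect_gt(nrow(mp), 0)
  w <- nchar(sim$config$motif_consensus)
  for (i in seq_len(nrow(mp))) {
    found <- as.character(Biostrings::subseq(seqs[[mp$chrom[i]]],
                                             mp$pos[i] + 1L, mp$pos[i] + w))
    expect_equal(found, sim$config$motif_consensus)
  }
})

test_that("methylated counts never exceed coverage and files round-trip", {
  sim <- small_sim()
  expect_true(all(sim$cpg$meth <= sim$cpg$cov))
  s <- sim$samples$sample_id[1]
  d <- read_coverage(sim$paths$coverage[[s]])
  expect_equal(d$meth, unname(sim$cpg$meth[, s]))
  expect_equal(d$meth + d$unmeth, unname(sim$cpg$cov[, s]))
})

test_that("degenerate configurations behave at the boundaries", {
  cfg0 <- small_config(seed = 3, coverage_mean = 0)
  g <- simulate_genome(cfg0)
  cov0 <- simulate_coverage(cfg0, g$cpg, g$truth)
  expect_true(all(cov0$cov == 0L))

  cfg1 <- small_config(seed = 3, baseline_meth = 1, enhancer_hypometh = 1,
                       tf_peak_base = 1, ko_enhancer_delta = 0,
                       tf_ko_delta = 0, wt_il1b_global_delta = 0,
                       sample_noise_kappa = Inf)
  g1 <- simulate_genome(cfg1)
  cov1 <- simulate_coverage(cfg1, g1$cpg, g1$truth)
  expect_true(all(cov1$meth == cov1$cov))
})

test_that("planted enhancer DMRs recover the configured KO shift", {
  sim <- small_sim()
  cfg <- sim$config
  layout <- sim$truth$windows
  enh_idx <- which(layout$role == "enhancer")
  samples <- sim$samples
  wt <- samples$sample_id[samples$genotype == "WT" &
                            samples$treatment == "vehicle"]
  ko <- samples$sample_id[samples$genotype == "KO" &
                            samples$treatment == "vehicle"]
  deltas <- vapply(enh_idx, function(r) {
    rows <- layout$first_idx[r]:layout$last_idx[r]
    pwt <- 100 * sum(sim$cpg$meth[rows, wt]) / sum(sim$cpg$cov[rows, wt])
    pko <- 100 * sum(sim$cpg$meth[rows, ko]) / sum(sim$cpg$cov[rows, ko])
    pko - pwt
  }, numeric(1))
  expect_lt(abs(mean(deltas) - cfg$ko_enhancer_delta), 5)
})

test_that("emitted annotation files are consistent with the configuration", {
  sim <- small_sim()
  cfg <- sim$config
  for (tf in cfg$tf_names) {
    peaks <- read_bed(sim$paths$tf[[tf]])
    expect_equal(nrow(peaks), cfg$n_tf_peaks)
  }
  de <- read_de_table(sim$paths$de_table)
  expect_equal(anyDuplicated(de$gene_id), 0L)
  expect_equal(nrow(de), cfg$n_target_genes + cfg$n_background_genes)
  # promoter-overlapping decoy K27 peaks are recorded as non-enhancers
  dec <- sim$truth$non_enhancer_peaks
  prom_dec <- dec[dec$reason == "promoter_overlap", ]
  expect_gt(nrow(prom_dec), 0)
  prom <- read_bed(sim$paths$promoters)
  for (i in seq_len(nrow(prom_dec))) {
    ov <- any(prom$chrom == prom_dec$chrom[i] &
                prom$start < prom_dec$end[i] & prom_dec$start[i] < prom$end)
    expect_true(ov)
  }
})
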