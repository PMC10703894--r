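# Synthetic methylome generator. Emulates a 2x2 genotype (WT/KO) x
# treatment (vehicle/IL1B) whole-genome bisulfite design on a small genome:
# negative-binomial read coverage per CpG, binomial methylation counts
# around region-level probabilities, enhancer-localised hypermethylation
# planted in the KO, a global methylation reduction in treated WT samples,
# TF ChIP peaks with a planted KO shift for selected factors, histone-mark
# peaks constructed so the enhancer classifier's truth labels are exactly
# recoverable, motif instances embedded in enhancers, and a DE table whose
# most significant downregulated genes are the planted target genes. The
# seed fully determines every output; a truth table records all planted
# features. Feature placement is aligned to whole 50-CpG probe windows so
# planted differential regions correspond one-to-one to tested probes.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic methylome.
#' Methylation probabilities are on [0, 1]; deltas are in percentage
#' points. The defaults define the package's reference study conditions:
#' a 2 Mb CpG-condensed genome yielding roughly 800 fifty-CpG probes, a
#' 4-vs-4 replicate design per arm, 100 two-probe enhancers carrying a
#' +30 pp KO hypermethylation, one TF with a +25 pp KO shift at its 120
#' binding sites, and a -8 pp global shift in IL1B-treated WT samples.
#'
#' @param seed Integer seed; determines all outputs.
#' @param genome_length_bp Total genome length (default 2e6).
#' @param n_chromosomes Number of equally sized chromosomes (default 2).
#' @param cpg_density Fraction of dinucleotides that are CpG (default 0.02).
#' @param n_samples_per_group Replicates per genotype x treatment group
#'   (default 4).
#' @param groups Data frame with columns `genotype` (WT/KO) and `treatment`
#'   (vehicle/IL1B); default full 2x2.
#' @param coverage_mean Mean reads per CpG (default 20).
#' @param coverage_dispersion Negative-binomial dispersion (`size =
#'   1/dispersion`; 0 gives Poisson coverage). Default 0.2.
#' @param baseline_meth Genome-background methylation probability (0.75).
#' @param enhancer_hypometh Methylation probability inside enhancers (0.25).
#' @param ko_enhancer_delta Added methylation (pp) in KO at planted
#'   enhancer DMRs (default +30).
#' @param wt_il1b_global_delta Global methylation shift (pp) in treated WT
#'   samples (default -8).
#' @param n_enhancers_per_state Enhancers per cell state (default 25).
#' @param states Cell state labels (default HSC, CMP, GMP, MEP).
#' @param enhancer_probes Whole probe windows per enhancer (default 2).
#' @param n_decoy_peaks_per_state Non-enhancer H3K27ac decoy peaks per
#'   state, cycling through the three failure modes (default 6).
#' @param tf_names TF ChIP peak sets to simulate.
#' @param hyper_tfs TFs whose binding sites carry the planted KO shift.
#' @param tf_ko_delta Added methylation (pp) in KO at hyper-TF windows
#'   (default +25).
#' @param tf_peak_base Base methylation probability at TF peak windows
#'   (default 0.40, so the KO shift stays inside [0, 1]).
#' @param n_tf_peaks ChIP peaks per TF (default 120).
#' @param tf_peak_cpgs CpGs per TF peak (default 10).
#' @param n_target_genes Downregulated genes planted next to hyper-TF
#'   peaks (default 40).
#' @param n_background_genes Background genes with null DE statistics
#'   (default 160).
#' @param sample_noise_kappa Beta concentration for per-sample,
#'   per-window methylation jitter; `Inf` disables jitter (default 200,
#'   i.e. a replicate-level standard deviation of about 3 pp at p = 0.75).
#' @param window_cpgs CpGs per probe window (default 50).
#' @param motif_fraction Fraction of enhancers carrying a planted motif
#'   instance (default 0.8).
#' @param motif_consensus Planted motif consensus; must contain no CG
#'   dinucleotide so planting leaves CpG positions untouched (default
#'   `ATGACTCATT`, an AP-1-like site).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length_bp = 2e6,
                       n_chromosomes = 2L,
                       cpg_density = 0.02,
                       n_samples_per_group = 4L,
                       groups = data.frame(
                         genotype = c("WT", "WT", "KO", "KO"),
                         treatment = c("vehicle", "IL1B", "vehicle", "IL1B"),
                         stringsAsFactors = FALSE),
                       coverage_mean = 20,
                       coverage_dispersion = 0.2,
                       baseline_meth = 0.75,
                       enhancer_hypometh = 0.25,
                       ko_enhancer_delta = 30,
                       wt_il1b_global_delta = -8,
                       n_enhancers_per_state = 25L,
                       states = c("HSC", "CMP", "GMP", "MEP"),
                       enhancer_probes = 2L,
                       n_decoy_peaks_per_state = 6L,
                       tf_names = c("Spi1", "Cebpa", "Gata1", "Runx1"),
                       hyper_tfs = "Spi1",
                       tf_ko_delta = 25,
                       tf_peak_base = 0.40,
                       n_tf_peaks = 120L,
                       tf_peak_cpgs = 10L,
                       n_target_genes = 40L,
                       n_background_genes = 160L,
                       sample_noise_kappa = 200,
                       window_cpgs = 50L,
                       motif_fraction = 0.8,
                       motif_consensus = "ATGACTCATT") {
  cfg <- list(seed = as.integer(seed), genome_length_bp = genome_length_bp,
              n_chromosomes = as.integer(n_chromosomes),
              cpg_density = cpg_density,
              n_samples_per_group = as.integer(n_samples_per_group),
              groups = groups, coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              baseline_meth = baseline_meth,
              enhancer_hypometh = enhancer_hypometh,
              ko_enhancer_delta = ko_enhancer_delta,
              wt_il1b_global_delta = wt_il1b_global_delta,
              n_enhancers_per_state = as.integer(n_enhancers_per_state),
              states = states, enhancer_probes = as.integer(enhancer_probes),
              n_decoy_peaks_per_state = as.integer(n_decoy_peaks_per_state),
              tf_names = tf_names, hyper_tfs = hyper_tfs,
              tf_ko_delta = tf_ko_delta, tf_peak_base = tf_peak_base,
              n_tf_peaks = as.integer(n_tf_peaks),
              tf_peak_cpgs = as.integer(tf_peak_cpgs),
              n_target_genes = as.integer(n_target_genes),
              n_background_genes = as.integer(n_background_genes),
              sample_noise_kappa = sample_noise_kappa,
              window_cpgs = as.integer(window_cpgs),
              motif_fraction = motif_fraction,
              motif_consensus = toupper(motif_consensus))
  probs <- c(cfg$baseline_meth, cfg$enhancer_hypometh, cfg$tf_peak_base)
  if (any(probs < 0 | probs > 1))
    stop("methylation probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$cpg_density <= 0 || cfg$cpg_density >= 0.5)
    stop("cpg_density must be in (0, 0.5)", call. = FALSE)
  if (!all(c("genotype", "treatment") %in% names(cfg$groups)))
    stop("groups must have genotype and treatment columns", call. = FALSE)
  if (cfg$n_samples_per_group < 2)
    stop("groups must contain at least 2 samples each", call. = FALSE)
  if (cfg$n_tf_peaks > 0 && cfg$window_cpgs < 45)
    stop("window_cpgs must be >= 45 to host TF peaks", call. = FALSE)
  if (grepl("CG", cfg$motif_consensus))
    stop("motif_consensus must not contain a CG dinucleotide", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config A `sim_config`.
#' @return Data frame `sample_id`, `genotype`, `treatment`.
#' @export
sim_samples <- function(config) {
  rows <- lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups$genotype[i]; t <- config$groups$treatment[i]
    data.frame(sample_id = sprintf("%s_%s_%d", g, t,
                                   seq_len(config$n_samples_per_group)),
               genotype = g, treatment = t, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default PWM set matching the simulator
#'
#' The planted AP-1-like motif plus two decoy motifs that are never
#' planted, for use as the known-motif collection in enrichment runs.
#'
#' @param consensus Planted consensus (default as in [sim_config()]).
#' @return Named list of `pwm` objects.
#' @export
default_pwms <- function(consensus = "ATGACTCATT") {
  list(AP1_like = consensus_pwm("AP1_like", consensus),
       ETS_like = consensus_pwm("ETS_like", "ACCGGAAGTG"),
       GATA_like = consensus_pwm("GATA_like", "CAGATAAGAT"))
}

cg_positions <- function(code) {
  n <- length(code)
  which(code[-n] == 2L & code[-1] == 3L)  # 1-based index of the C
}

# ---- genome -----------------------------------------------------------

#' Simulate the genome sequence and feature layout
#'
#' Generates random chromosome sequences thinned to the target CpG
#' density, tiles them into whole probe windows, allocates windows to
#' planted features (enhancers spanning `enhancer_probes` consecutive
#' windows, TF-peak windows, decoy-peak windows), and embeds motif
#' consensus instances in a fraction of enhancers. Motif planting is
#' CpG-neutral: instances are only placed at offsets where the replacement
#' cannot create or destroy a CG dinucleotide, so the CpG position list is
#' exact for the final sequence. Windows adjacent to enhancers are left
#' unused as a buffer so that promoters and genes placed later can never
#' bleed into an enhancer.
#'
#' @param config A `sim_config`.
#' @return List with `genome` (named `DNAStringSet`), `cpg` (data frame
#'   `chrom`, `pos`, 0-based positions of the C of each CpG), `truth`
#'   (window layout, planted DMR intervals, enhancer/TF/motif truth), and
#'   `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chrom_len <- floor(config$genome_length_bp / config$n_chromosomes)
  chroms <- sprintf("chrS%d", seq_len(config$n_chromosomes))
  codes <- list()
  for (ch in chroms) {
    code <- sample.int(4L, chrom_len, replace = TRUE)
    cg <- cg_positions(code)
    target <- round(config$cpg_density * (chrom_len - 1))
    if (length(cg) < target)
      stop("cannot reach requested cpg_density ", config$cpg_density,
           call. = FALSE)
    drop <- sort(sample(cg, length(cg) - target))
    code[drop + 1L] <- sample(c(1L, 4L), length(drop), replace = TRUE)
    codes[[ch]] <- code
  }
  cpg <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch, pos = cg_positions(codes[[ch]]) - 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(cpg) <- NULL
  win <- tile_probes(cpg, window_cpgs = config$window_cpgs)
  layout <- allocate_windows(win, config)
  truth <- build_feature_truth(layout, cpg, config)
  planted <- plant_motifs(codes, truth, cpg, config)
  codes <- planted$codes
  truth <- planted$truth
  # planting is CpG-neutral by construction; verify
  for (ch in chroms)
    stopifnot(identical(cg_positions(codes[[ch]]) - 1L,
                        cpg$pos[cpg$chrom == ch]))
  seqs <- Biostrings::DNAStringSet(vapply(codes, function(code)
    paste(c("A", "C", "G", "T")[code], collapse = ""), character(1)))
  names(seqs) <- chroms
  list(genome = seqs, cpg = cpg, truth = truth, config = config)
}

# assign windows to feature roles; windows flanking enhancers become buffer
allocate_windows <- function(win, config) {
  W <- nrow(win)
  layout <- win
  layout$widx <- seq_len(W)
  layout$role <- rep("background", W)
  layout$state <- layout$tf <- layout$decoy_type <- rep(NA_character_, W)
  layout$enh_id <- rep(NA_integer_, W)
  layout$buffer <- rep(FALSE, W)
  n_enh <- config$n_enhancers_per_state * length(config$states)
  ep <- config$enhancer_probes
  if (n_enh > 0) {
    if (W < ep)
      stop("genome_length_bp too small: no complete probe windows",
           call. = FALSE)
    run_ok <- vapply(seq_len(W - ep + 1), function(i)
      layout$chrom[i] == layout$chrom[i + ep - 1], logical(1))
    cand <- which(run_ok)
    for (e in seq_len(n_enh)) {
      if (!length(cand))
        stop("genome_length_bp too small to host ", n_enh, " enhancers of ",
             ep, " probe windows each", call. = FALSE)
      i <- if (length(cand) == 1) cand else sample(cand, 1)
      idx <- i:(i + ep - 1)
      layout$role[idx] <- "enhancer"
      layout$state[idx] <- config$states[ceiling(e / config$n_enhancers_per_state)]
      layout$enh_id[idx] <- e
      if (i > 1 && layout$chrom[i - 1] == layout$chrom[i])
        layout$buffer[i - 1] <- TRUE
      j <- i + ep
      if (j <= W && layout$chrom[j] == layout$chrom[i])
        layout$buffer[j] <- TRUE
      cand <- setdiff(cand, (i - ep):(i + ep))
    }
  }
  pool <- function() which(layout$role == "background" & !layout$buffer)
  take <- function(n, what) {
    p <- pool()
    if (length(p) < n)
      stop("genome_length_bp too small to host ", what, ": need ", n,
           " free probe windows, have ", length(p), call. = FALSE)
    if (length(p) == 1) p else sort(sample(p, n))
  }
  if (config$n_tf_peaks > 0) {
    wins_per_tf <- ceiling(config$n_tf_peaks / 2)
    for (tf in config$tf_names) {
      idx <- take(wins_per_tf, paste0("TF peaks for ", tf))
      layout$role[idx] <- if (tf %in% config$hyper_tfs) "tf_hyper" else "tf_bg"
      layout$tf[idx] <- tf
    }
  }
  n_decoy <- config$n_decoy_peaks_per_state
  if (n_decoy > 0) {
    types <- c("me3", "promoter", "no_me1")
    for (st in config$states) {
      idx <- take(n_decoy, paste0("decoy peaks for ", st))
      layout$role[idx] <- "decoy"
      layout$state[idx] <- st
      layout$decoy_type[idx] <- rep_len(types, n_decoy)
    }
  }
  layout
}

# positions of the k-th..(k+m-1)-th CpGs of a window, as an interval
window_cpg_interval <- function(layout_row, cpg, from, to) {
  p <- cpg$pos[layout_row$first_idx:layout_row$last_idx]
  c(start = p[from], end = p[to] + 2L)
}

build_feature_truth <- function(layout, cpg, config) {
  enh <- NULL
  enh_rows <- which(layout$role == "enhancer")
  enhancers <- NULL
  if (length(enh_rows)) {
    by_id <- split(enh_rows, layout$enh_id[enh_rows])
    enhancers <- do.call(rbind, lapply(names(by_id), function(id) {
      rows <- by_id[[id]]
      data.frame(chrom = layout$chrom[rows[1]],
                 start = min(layout$start[rows]),
                 end = max(layout$end[rows]),
                 name = sprintf("enh_%s_%03d", layout$state[rows[1]],
                                as.integer(id)),
                 score = NA_real_, strand = NA_character_,
                 state = layout$state[rows[1]],
                 enh_id = as.integer(id), stringsAsFactors = FALSE)
    }))
    enhancers <- order_intervals(enhancers)
    rownames(enhancers) <- NULL
  }
  # TF peaks: up to two per allocated window over runs of tf_peak_cpgs CpGs
  tf_peaks <- stats::setNames(vector("list", length(config$tf_names)),
                              config$tf_names)
  m <- config$tf_peak_cpgs
  for (tf in config$tf_names) {
    rows <- which(layout$tf %in% tf)
    if (!length(rows)) { tf_peaks[[tf]] <- empty_intervals(); next }
    peaks <- list()
    slots <- list(c(4L, 4L + m - 1L), c(31L, 31L + m - 1L))
    k <- 0L
    for (r in rows) for (s in slots) {
      if (k >= config$n_tf_peaks) break
      iv <- window_cpg_interval(layout[r, ], cpg, s[1], s[2])
      k <- k + 1L
      peaks[[k]] <- data.frame(chrom = layout$chrom[r],
                               start = unname(iv["start"]),
                               end = unname(iv["end"]),
                               name = sprintf("%s_peak%04d", tf, k),
                               score = NA_real_, strand = NA_character_,
                               stringsAsFactors = FALSE)
    }
    tf_peaks[[tf]] <- do.call(rbind, peaks)
    rownames(tf_peaks[[tf]]) <- NULL
  }
  # planted DMR intervals: enhancer spans (+ko_enhancer_delta) and
  # hyper-TF windows (+tf_ko_delta), all hypermethylated in KO
  dmrs <- list()
  if (!is.null(enhancers))
    dmrs$enh <- data.frame(chrom = enhancers$chrom, start = enhancers$start,
                           end = enhancers$end, direction = "hyper",
                           delta_pp = config$ko_enhancer_delta,
                           class = "enhancer", stringsAsFactors = FALSE)
  hyp <- which(layout$role == "tf_hyper")
  if (length(hyp))
    dmrs$tf <- data.frame(chrom = layout$chrom[hyp],
                          start = layout$start[hyp], end = layout$end[hyp],
                          direction = "hyper",
                          delta_pp = config$tf_ko_delta,
                          class = "tf_peak", stringsAsFactors = FALSE)
  planted <- if (length(dmrs)) {
    x <- do.call(rbind, dmrs); rownames(x) <- NULL; order_intervals(x)
  } else NULL
  list(windows = layout, enhancers = enhancers, tf_peaks = tf_peaks,
       planted_dmrs = planted, motif_positions = NULL, genes = NULL,
       target_genes = NULL, config = config)
}

# embed the motif consensus in a fraction of enhancers at offsets where no
# CG dinucleotide can be created or destroyed
plant_motifs <- function(codes, truth, cpg, config) {
  enh <- truth$enhancers
  if (is.null(enh) || nrow(enh) == 0 || config$motif_fraction <= 0)
    return(list(codes = codes, truth = truth))
  mot <- match(strsplit(config$motif_consensus, "")[[1]],
               c("A", "C", "G", "T"))
  w <- length(mot)
  n_plant <- round(config$motif_fraction * nrow(enh))
  chosen <- sort(sample(nrow(enh), n_plant))
  placed <- list()
  for (e in chosen) {
    ch <- enh$chrom[e]
    cpos <- cpg$pos[cpg$chrom == ch]  # 0-based
    lo <- enh$start[e] + 20L
    hi <- enh$end[e] - w - 20L
    if (hi <= lo) next
    offs <- lo:hi
    # offset i (0-based) replaces chars [i, i+w); CGs starting in
    # [i-1, i+w-1] would be affected, so require none there
    ok <- vapply(offs, function(i)
      !any(cpos >= i - 1L & cpos <= i + w - 1L), logical(1))
    if (!any(ok)) next
    i <- offs[ok][sample(sum(ok), 1)]
    codes[[ch]][(i + 1L):(i + w)] <- mot
    placed[[length(placed) + 1L]] <-
      data.frame(chrom = ch, pos = i, strand = "+",
                 motif_id = "AP1_like", enhancer = enh$name[e],
                 stringsAsFactors = FALSE)
  }
  truth$motif_positions <- if (length(placed)) do.call(rbind, placed) else NULL
  list(codes = codes, truth = truth)
}

# ---- coverage ---------------------------------------------------------

#' Simulate per-sample CpG methylation coverage
#'
#' For every CpG and sample, coverage is drawn from a negative binomial
#' with mean `coverage_mean` (Poisson when `coverage_dispersion` is 0) and
#' the methylated count binomially with a probability composed of the
#' window's base level, the genotype/treatment shifts, and per-sample
#' per-window Beta jitter (concentration `sample_noise_kappa`), clamped to
#' [0, 1]. All CpGs of one window share a sample's jitter draw, which is
#' what gives probes replicate-level variance.
#'
#' @param config A `sim_config`.
#' @param cpg CpG position data frame from [simulate_genome()].
#' @param truth Truth list from [simulate_genome()] (uses the window
#'   layout).
#' @return A `cpg_matrix` across all samples of the design.
#' @export
simulate_coverage <- function(config, cpg, truth) {
  set.seed(config$seed + 1L)
  layout <- truth$windows
  n <- nrow(cpg)
  region <- rep(NA_integer_, n)
  for (i in seq_len(nrow(layout)))
    region[layout$first_idx[i]:layout$last_idx[i]] <- i
  chroms <- unique(cpg$chrom)
  tail_region <- nrow(layout) + match(cpg$chrom, chroms)
  region[is.na(region)] <- tail_region[is.na(region)]
  n_regions <- nrow(layout) + length(chroms)
  base <- rep(config$baseline_meth, n_regions)
  kodelta <- rep(0, n_regions)
  if (nrow(layout)) {
    base[seq_len(nrow(layout))] <- ifelse(
      layout$role == "enhancer", config$enhancer_hypometh,
      ifelse(layout$role == "tf_hyper", config$tf_peak_base,
             config$baseline_meth))
    kodelta[seq_len(nrow(layout))] <- ifelse(
      layout$role == "enhancer", config$ko_enhancer_delta,
      ifelse(layout$role == "tf_hyper", config$tf_ko_delta, 0))
  }
  samples <- sim_samples(config)
  S <- nrow(samples)
  meth <- cov <- matrix(0L, n, S, dimnames = list(NULL, samples$sample_id))
  kappa <- config$sample_noise_kappa
  size <- if (config$coverage_dispersion > 0) 1 / config$coverage_dispersion
    else Inf
  for (s in seq_len(S)) {
    ko <- samples$genotype[s] == "KO"
    wt_il1b <- samples$genotype[s] == "WT" & samples$treatment[s] == "IL1B"
    pr <- clamp01(base + ko * kodelta / 100 +
                    wt_il1b * config$wt_il1b_global_delta / 100)
    if (is.finite(kappa)) {
      inner <- pr > 0 & pr < 1
      pr[inner] <- stats::rbeta(sum(inner), kappa * pr[inner],
                                kappa * (1 - pr[inner]))
    }
    p_cpg <- pr[region]
    cv <- if (config$coverage_mean <= 0) {
      integer(n)
    } else if (is.finite(size)) {
      stats::rnbinom(n, mu = config$coverage_mean, size = size)
    } else {
      stats::rpois(n, config$coverage_mean)
    }
    meth[, s] <- stats::rbinom(n, cv, p_cpg)
    cov[, s] <- cv
  }
  new_cpg_matrix(cpg$chrom, cpg$pos, meth, cov, samples$sample_id)
}

# ---- annotations ------------------------------------------------------

#' Simulate annotation inputs: histone peaks, promoters, genes, DE table
#'
#' Constructs the histone-mark peak sets so the enhancer classifier's
#' truth labels are exactly recoverable (true enhancers carry H3K27ac +
#' H3K4me1, no H3K4me3, no promoter overlap; decoys violate exactly one
#' rule each), places target genes within 2 kb of hyper-TF peaks and
#' background genes inside background windows, derives strand-aware
#' promoters and CpG islands, and emits a DE table in which the planted
#' target genes are the most significantly downregulated entries.
#'
#' @param config A `sim_config`.
#' @param truth Truth list from [simulate_genome()].
#' @return List with `histone_peaks` (state -> list of H3K27ac/H3K4me1/
#'   H3K4me3 interval tables), `promoters`, `cpg_islands`, `genes`,
#'   `de_table`, `non_enhancer_peaks`, and the updated `truth` (adds
#'   `genes`, `target_genes`, `non_enhancer_peaks`).
#' @export
simulate_annotations <- function(config, truth) {
  set.seed(config$seed + 2L)
  layout <- truth$windows
  histone <- stats::setNames(lapply(config$states, function(st)
    list(H3K27ac = list(), H3K4me1 = list(), H3K4me3 = list())),
    config$states)
  non_enh <- list()
  extra_promoters <- list()
  # true enhancers
  if (!is.null(truth$enhancers)) {
    for (i in seq_len(nrow(truth$enhancers))) {
      e <- truth$enhancers[i, ]
      st <- e$state
      histone[[st]]$H3K27ac[[length(histone[[st]]$H3K27ac) + 1L]] <-
        new_intervals(e$chrom, e$start, e$end,
                      name = sub("^enh", "k27", e$name),
                      score = round(stats::runif(1, 5, 50), 2))
      histone[[st]]$H3K4me1[[length(histone[[st]]$H3K4me1) + 1L]] <-
        new_intervals(e$chrom, e$start + 50L, e$end - 50L,
                      name = sub("^enh", "me1", e$name),
                      score = round(stats::runif(1, 5, 30), 2))
    }
  }
  # decoy peaks: each violates exactly one enhancer rule
  dec <- which(layout$role == "decoy")
  for (r in dec) {
    st <- layout$state[r]
    type <- layout$decoy_type[r]
    s0 <- layout$start[r] + 20L
    e0 <- layout$end[r] - 20L
    nm <- sprintf("decoy_%s_%s_w%d", st, type, layout$widx[r])
    histone[[st]]$H3K27ac[[length(histone[[st]]$H3K27ac) + 1L]] <-
      new_intervals(layout$chrom[r], s0, e0, name = nm,
                    score = round(stats::runif(1, 5, 50), 2))
    if (type == "me3") {
      histone[[st]]$H3K4me1[[length(histone[[st]]$H3K4me1) + 1L]] <-
        new_intervals(layout$chrom[r], s0 + 10L, e0 - 10L,
                      name = paste0(nm, "_me1"),
                      score = round(stats::runif(1, 5, 30), 2))
      histone[[st]]$H3K4me3[[length(histone[[st]]$H3K4me3) + 1L]] <-
        new_intervals(layout$chrom[r], s0 + 10L, e0 - 10L,
                      name = paste0(nm, "_me3"),
                      score = round(stats::runif(1, 20, 60), 2))
      reason <- "H3K4me3_present"
    } else if (type == "promoter") {
      histone[[st]]$H3K4me1[[length(histone[[st]]$H3K4me1) + 1L]] <-
        new_intervals(layout$chrom[r], s0 + 10L, e0 - 10L,
                      name = paste0(nm, "_me1"),
                      score = round(stats::runif(1, 5, 30), 2))
      extra_promoters[[length(extra_promoters) + 1L]] <-
        new_intervals(layout$chrom[r], s0 + 10L, s0 + 510L,
                      name = paste0(nm, "_prom"))
      reason <- "promoter_overlap"
    } else {
      reason <- "no_H3K4me1"
    }
    non_enh[[length(non_enh) + 1L]] <-
      data.frame(chrom = layout$chrom[r], start = s0, end = e0, name = nm,
                 state = st, reason = reason, stringsAsFactors = FALSE)
  }
  histone <- lapply(histone, function(h) lapply(h, function(l)
    if (length(l)) order_intervals(do.call(rbind, l)) else empty_intervals()))
  # genes: targets next to hyper-TF peaks, background genes in background
  # windows; genes stay clear of enhancer windows by construction (TF and
  # background windows are never adjacent to enhancers)
  genes <- list()
  hyper_peaks <- do.call(rbind, truth$tf_peaks[config$hyper_tfs])
  n_target <- min(config$n_target_genes,
                  if (is.null(hyper_peaks)) 0L else nrow(hyper_peaks))
  if (n_target > 0) {
    sel <- sort(sample(nrow(hyper_peaks), n_target))
    for (i in seq_len(n_target)) {
      pk <- hyper_peaks[sel[i], ]
      gap <- sample(200:1500, 1)
      len <- sample(1500:3500, 1)
      strand <- if (i %% 2 == 1) "+" else "-"
      if (strand == "+") {
        gs <- pk$end + gap; ge <- gs + len
      } else {
        ge <- pk$start - gap; gs <- ge - len
      }
      if (gs < 0) next
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = sprintf("gene_t%03d", i), chrom = pk$chrom,
                   start = gs, end = ge, strand = strand, is_target = TRUE,
                   near_peak = pk$name, stringsAsFactors = FALSE)
    }
  }
  bgw <- which(layout$role == "background" & !layout$buffer)
  if (config$n_background_genes > 0 && length(bgw)) {
    pickw <- sample(bgw, config$n_background_genes, replace = TRUE)
    for (i in seq_len(config$n_background_genes)) {
      r <- pickw[i]
      width <- layout$end[r] - layout$start[r]
      len <- min(sample(1000:2000, 1), width - 200L)
      gs <- layout$start[r] + 100L
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = sprintf("gene_b%03d", i), chrom = layout$chrom[r],
                   start = gs, end = gs + len,
                   strand = sample(c("+", "-"), 1), is_target = FALSE,
                   near_peak = NA_character_, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  # strand-aware promoters (TSS-1000 .. TSS+500) and CpG islands
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0L, as.integer(
                       ifelse(genes$strand == "+", tss - 1000L, tss - 500L))),
                     end = as.integer(
                       ifelse(genes$strand == "+", tss + 500L, tss + 1000L)),
                     name = paste0(genes$gene_id, "_prom"),
                     score = NA_real_, strand = genes$strand,
                     stringsAsFactors = FALSE)
  if (length(extra_promoters))
    prom <- rbind(prom, do.call(rbind, extra_promoters))
  prom <- order_intervals(prom)
  rownames(prom) <- NULL
  bg_idx <- which(!genes$is_target)
  isl_idx <- utils::head(bg_idx, 30)
  islands <- if (length(isl_idx)) {
    order_intervals(data.frame(
      chrom = genes$chrom[isl_idx],
      start = pmax(0L, as.integer(tss[isl_idx] - 300L)),
      end = as.integer(tss[isl_idx] + 300L),
      name = paste0(genes$gene_id[isl_idx], "_cgi"),
      score = NA_real_, strand = NA_character_, stringsAsFactors = FALSE))
  } else empty_intervals()
  rownames(islands) <- NULL
  # DE table: targets strongly and significantly down, background null
  n_g <- nrow(genes)
  log2fc <- stats::rnorm(n_g, 0, 0.8)
  pval <- stats::runif(n_g, 0.01, 1)
  tgt <- genes$is_target
  log2fc[tgt] <- -stats::runif(sum(tgt), 1.5, 3)
  pval[tgt] <- 10^(-stats::runif(sum(tgt), 8, 12))
  de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, pvalue = pval,
                   stringsAsFactors = FALSE)
  de$qvalue <- stats::p.adjust(de$pvalue, method = "BH")
  non_enh <- if (length(non_enh)) do.call(rbind, non_enh) else NULL
  truth$genes <- genes
  truth$target_genes <- genes$gene_id[genes$is_target]
  truth$non_enhancer_peaks <- non_enh
  list(histone_peaks = histone, promoters = prom, cpg_islands = islands,
       genes = genes, de_table = de, non_enhancer_peaks = non_enh,
       truth = truth)
}

# ---- orchestration ----------------------------------------------------

#' Simulate a complete methylome study and write all pipeline inputs
#'
#' Runs [simulate_genome()], [simulate_annotations()] and
#' [simulate_coverage()] and writes every input file the analysis pipeline
#' consumes: genome FASTA, one bismark-style coverage file per sample,
#' histone-mark and TF peak BEDs, promoter/CpG-island BEDs, a gene table,
#' the DE table, and the truth table files. Identical configurations
#' (including the seed) produce byte-identical output sets.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return List with `config`, `outdir`, `paths` (named file manifest),
#'   `truth`, `samples`, `cpg` (the simulated `cpg_matrix`), `genome`,
#'   and `annotations`.
#' @export
simulate_methylome <- function(config, outdir) {
  g <- simulate_genome(config)
  ann <- simulate_annotations(config, g$truth)
  truth <- ann$truth
  cpgm <- simulate_coverage(config, g$cpg, truth)
  samples <- sim_samples(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("coverage", "peaks", "annot", "truth"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  paths <- list(genome = file.path(outdir, "genome.fa"))
  write_fasta(g$genome, paths$genome)
  paths$coverage <- stats::setNames(
    file.path(outdir, "coverage", paste0(samples$sample_id, ".cov")),
    samples$sample_id)
  for (s in samples$sample_id)
    write_coverage(cpg_sample_frame(cpgm, s), paths$coverage[[s]])
  for (st in names(ann$histone_peaks))
    for (mark in names(ann$histone_peaks[[st]])) {
      p <- file.path(outdir, "peaks", sprintf("%s_%s.bed", mark, st))
      paths$histone <- c(paths$histone, stats::setNames(p, paste(mark, st)))
      write_bed(ann$histone_peaks[[st]][[mark]], p)
    }
  paths$tf <- stats::setNames(
    file.path(outdir, "peaks", sprintf("TF_%s.bed", names(truth$tf_peaks))),
    names(truth$tf_peaks))
  for (tf in names(truth$tf_peaks)) write_bed(truth$tf_peaks[[tf]],
                                              paths$tf[[tf]])
  paths$promoters <- file.path(outdir, "annot", "promoters.bed")
  write_bed(ann$promoters, paths$promoters)
  paths$cpg_islands <- file.path(outdir, "annot", "cpg_islands.bed")
  write_bed(ann$cpg_islands, paths$cpg_islands)
  paths$genes <- file.path(outdir, "annot", "genes.tsv")
  write_results_tsv(ann$genes[, c("gene_id", "chrom", "start", "end",
                                  "strand")], paths$genes)
  paths$de_table <- file.path(outdir, "de_table.tsv")
  write_results_tsv(ann$de_table, paths$de_table)
  # truth table files
  paths$truth <- c(
    planted_dmrs = file.path(outdir, "truth", "planted_dmrs.tsv"),
    enhancers = file.path(outdir, "truth", "enhancers.tsv"),
    motif_positions = file.path(outdir, "truth", "motif_positions.tsv"),
    target_genes = file.path(outdir, "truth", "target_genes.txt"),
    windows = file.path(outdir, "truth", "windows.tsv"),
    config = file.path(outdir, "truth", "config.json"))
  if (!is.null(truth$planted_dmrs))
    write_results_tsv(truth$planted_dmrs, paths$truth[["planted_dmrs"]])
  if (!is.null(truth$enhancers))
    write_results_tsv(truth$enhancers, paths$truth[["enhancers"]])
  if (!is.null(truth$motif_positions))
    write_results_tsv(truth$motif_positions, paths$truth[["motif_positions"]])
  writeLines(truth$target_genes %||% character(),
             paths$truth[["target_genes"]])
  write_results_tsv(truth$windows[, c("probe_id", "chrom", "start", "end",
                                      "widx", "role", "state", "tf",
                                      "buffer")],
                    paths$truth[["windows"]])
  jsonlite::write_json(unclass(config), paths$truth[["config"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(config = config, outdir = outdir, paths = paths, truth = truth,
       samples = samples, cpg = cpgm, genome = g$genome, annotations = ann)
}

#' Simulate probe-level counts directly (no genome)
#'
#' Generates a `probe_set` of `n_probes` windows with per-CpG
#' negative-binomial coverage and binomial methylated counts at the given
#' per-group methylation probabilities, without any genome, features or
#' jitter unless requested. Intended for calibration studies of the
#' differential test (all samples of a group share the probe's group
#' probability exactly when `sample_noise_kappa` is infinite).
#'
#' @param n_probes Number of probes.
#' @param p_a,p_b Group methylation probabilities; scalars or per-probe
#'   vectors.
#' @param n_per_group Samples per group (default 4).
#' @param n_cpgs CpGs per probe (default 50).
#' @param coverage_mean,coverage_dispersion Coverage model (defaults 20,
#'   0.2).
#' @param sample_noise_kappa Beta jitter concentration; `Inf` (default)
#'   disables jitter.
#' @param seed Optional seed.
#' @return A `probe_set` with samples `A1..An, B1..Bn`; group membership is
#'   recoverable from the sample prefix.
#' @export
simulate_null_probes <- function(n_probes, p_a = 0.75, p_b = p_a,
                                 n_per_group = 4L, n_cpgs = 50L,
                                 coverage_mean = 20,
                                 coverage_dispersion = 0.2,
                                 sample_noise_kappa = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_a <- rep_len(p_a, n_probes)
  p_b <- rep_len(p_b, n_probes)
  samples <- c(paste0("A", seq_len(n_per_group)),
               paste0("B", seq_len(n_per_group)))
  S <- length(samples)
  size <- if (coverage_dispersion > 0) 1 / coverage_dispersion else Inf
  meth <- cov <- covered <- matrix(0L, n_probes, S,
                                   dimnames = list(NULL, samples))
  for (s in seq_len(S)) {
    p <- if (s <= n_per_group) p_a else p_b
    if (is.finite(sample_noise_kappa)) {
      inner <- p > 0 & p < 1
      p[inner] <- stats::rbeta(sum(inner), sample_noise_kappa * p[inner],
                               sample_noise_kappa * (1 - p[inner]))
    }
    for (i in seq_len(n_probes)) {
      cv <- if (coverage_mean <= 0) integer(n_cpgs)
        else if (is.finite(size)) stats::rnbinom(n_cpgs, mu = coverage_mean,
                                                 size = size)
        else stats::rpois(n_cpgs, coverage_mean)
      mm <- stats::rbinom(n_cpgs, cv, p[i])
      meth[i, s] <- sum(mm)
      cov[i, s] <- sum(cv)
      covered[i, s] <- sum(cv > 0)
    }
  }
  width <- n_cpgs * 100L
  probes <- data.frame(
    probe_id = sprintf("sim_probe_%05d", seq_len(n_probes)),
    chrom = "chrSim", start = (seq_len(n_probes) - 1L) * width,
    end = seq_len(n_probes) * width,
    n_cpgs = n_cpgs, first_idx = NA_integer_, last_idx = NA_integer_,
    stringsAsFactors = FALSE)
  pct <- 100 * meth / cov
  pct[cov == 0] <- NA_real_
  structure(list(probes = probes, meth = meth, cov = cov,
                 covered_cpgs = covered, pct = pct, samples = samples),
            class = "probe_set")
}
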