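# Shared fixtures. The simulated studies are built once per test session
# and cached; every fixture is generated in code under a fixed seed.

fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 7L, ...) {
  sim_config(seed = seed, genome_length_bp = 4e5, n_chromosomes = 1L,
             states = c("HSC", "CMP"), n_enhancers_per_state = 3L,
             tf_names = c("TfA", "TfB"), hyper_tfs = "TfA",
             n_tf_peaks = 10L, n_decoy_peaks_per_state = 3L,
             n_target_genes = 5L, n_background_genes = 20L, ...)
}

small_sim <- function() {
  if (is.null(fixture_env$small_sim))
    fixture_env$small_sim <- simulate_methylome(
      small_config(), file.path(tempdir(), "methtile-small-sim"))
  fixture_env$small_sim
}

# small end-to-end run reused by annotation / motif tests
small_pipe <- function() {
  if (is.null(fixture_env$small_pipe))
    fixture_env$small_pipe <- run_methylome_pipeline(
      file.path(tempdir(), "methtile-small-pipe"), small_config(),
      min_tf_probes = 5L, top_n_genes = 10L, n_perm = 200L)
  fixture_env$small_pipe
}

# full default study (the package's reference conditions), seed 42;
# the wall time of the one real build is kept for the end-to-end check
default_pipe <- function() {
  if (is.null(fixture_env$default_pipe)) {
    t0 <- Sys.time()
    fixture_env$default_pipe <- run_methylome_pipeline(
      file.path(tempdir(), "methtile-default"), sim_config(seed = 42))
    fixture_env$default_pipe_secs <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  fixture_env$default_pipe
}

# hand-rolled probe_set from count matrices (columns are samples)
make_probe_set <- function(meth, cov, samples = colnames(meth),
                           n_cpgs = 50L) {
  n <- nrow(meth)
  probes <- data.frame(
    probe_id = sprintf("p%03d", seq_len(n)), chrom = rep("chrT", n),
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 500L,
    n_cpgs = rep(n_cpgs, n), first_idx = rep(NA_integer_, n),
    last_idx = rep(NA_integer_, n), stringsAsFactors = FALSE)
  pct <- 100 * meth / cov
  pct[cov == 0] <- NA_real_
  covered <- (cov > 0) * n_cpgs
  dimnames(meth) <- dimnames(cov) <- dimnames(pct) <- dimnames(covered) <-
    list(NULL, samples)
  structure(list(probes = probes, meth = meth, cov = cov,
                 covered_cpgs = covered, pct = pct, samples = samples),
            class = "probe_set")
}

# independent brute-force enrichment-score oracle (plain loop)
brute_es <- function(metric, hit, w = 1) {
  N <- length(metric)
  nh <- sum(hit)
  wts <- abs(metric)^w
  denom <- sum(wts[hit])
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) wts[i] / denom else -1 / (N - nh)
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# direct binomial log-likelihood LRT oracle at pooled proportions
direct_lrt <- function(m, u, grp) {
  ll <- function(m, u, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(m * log(p) + u * log(1 - p))
  }
  p0 <- sum(m) / sum(m + u)
  l0 <- ll(m, u, p0)
  l1 <- 0
  for (g in unique(grp)) {
    i <- grp == g
    pg <- sum(m[i]) / sum(m[i] + u[i])
    l1 <- l1 + ll(m[i], u[i], pg)
  }
  2 * (l1 - l0)
}
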