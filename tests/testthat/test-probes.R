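# Probe tiling, pooled quantification, the coverage filter and group
# summaries.

cpg_from_pos <- function(pos, meth, cov, samples = colnames(meth),
                         chrom = "chr1") {
  methtile:::new_cpg_matrix(rep(chrom, length(pos)), pos, meth, cov, samples)
}

test_that("tiling emits whole windows only and discards the remainder", {
  pos <- seq(0L, by = 10L, length.out = 100L)
  w <- tile_probes(data.frame(chrom = "chr1", pos = pos), window_cpgs = 50)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(pos[1], pos[51]))
  expect_equal(w$end, c(pos[50] + 2L, pos[100] + 2L))

  pos120 <- seq(0L, by = 10L, length.out = 120L)
  expect_equal(nrow(tile_probes(data.frame(chrom = "chr1", pos = pos120))), 2L)
  pos49 <- seq(0L, by = 10L, length.out = 49L)
  expect_equal(nrow(tile_probes(data.frame(chrom = "chr1", pos = pos49))), 0L)
})

test_that("probes never span chromosomes and partition the CpGs", {
  df <- data.frame(chrom = rep(c("chr1", "chr2"), c(75, 60)),
                   pos = c(seq(0, by = 5, length.out = 75),
                           seq(0, by = 5, length.out = 60)))
  w <- tile_probes(df, window_cpgs = 50)
  expect_equal(w$chrom, c("chr1", "chr2"))
  member <- unlist(Map(seq, w$first_idx, w$last_idx))
  expect_equal(length(member), length(unique(member)))  # no CpG in 2 probes
  expect_equal(length(member) + (75 - 50) + (60 - 50), nrow(df))
})

test_that("probe quantification pools counts across CpGs", {
  pos <- c(0L, 10L, 20L, 30L)
  meth <- matrix(c(3L, 1L, 0L, 0L), ncol = 1, dimnames = list(NULL, "s1"))
  cov <- matrix(c(4L, 4L, 0L, 0L), ncol = 1, dimnames = list(NULL, "s1"))
  cpg <- cpg_from_pos(pos, meth, cov)
  w <- tile_probes(cpg, window_cpgs = 4)
  ps <- quantify_probes(w, cpg)
  expect_equal(unname(ps$pct[1, "s1"]), 100 * 4 / 8)
  expect_equal(unname(ps$covered_cpgs[1, "s1"]), 2L)

  # invariant: pooled percentage depends only on totals, not the split
  meth2 <- matrix(c(1L, 3L, 0L, 0L), ncol = 1, dimnames = list(NULL, "s1"))
  ps2 <- quantify_probes(w, cpg_from_pos(pos, meth2, cov))
  expect_equal(ps$pct, ps2$pct)
})

test_that("zero-coverage probes are undefined, not zero", {
  pos <- c(0L, 10L)
  meth <- matrix(0L, 2, 1, dimnames = list(NULL, "s1"))
  cov <- matrix(0L, 2, 1, dimnames = list(NULL, "s1"))
  cpg <- cpg_from_pos(pos, meth, cov)
  ps <- quantify_probes(tile_probes(cpg, window_cpgs = 2), cpg)
  expect_true(is.na(ps$pct[1, "s1"]))
})

test_that("coverage filter requires the minimum in every sample and is monotone", {
  covered <- matrix(10L, 3, 8, dimnames = list(NULL, paste0("s", 1:8)))
  covered[2, 5] <- 9L   # fails in one sample
  covered[3, ] <- 0L
  ps <- make_probe_set(matrix(5L, 3, 8), matrix(10L, 3, 8),
                       samples = paste0("s", 1:8))
  ps$covered_cpgs <- covered
  kept <- apply_coverage_filter(ps, min_covered_cpgs = 10)
  expect_equal(attr(kept, "pass"), c(TRUE, FALSE, FALSE))

  for (thr in c(1, 5, 9, 10, 11)) {
    lo <- sum(attr(apply_coverage_filter(ps, min_covered_cpgs = thr), "pass"))
    hi <- sum(attr(apply_coverage_filter(ps, min_covered_cpgs = thr + 1),
                   "pass"))
    expect_lte(hi, lo)
  }
})

test_that("global methylation summary averages samples then probes", {
  meth <- matrix(75L, 4, 2, dimnames = list(NULL, c("a", "b")))
  cov <- matrix(100L, 4, 2, dimnames = list(NULL, c("a", "b")))
  ps <- make_probe_set(meth, cov)
  gs <- global_methylation_summary(ps, list(g = c("a", "b")))
  expect_equal(gs$mean_pct, 75)
  expect_equal(gs$sem, 0)

  meth2 <- matrix(c(40L, 60L), 2, 1, dimnames = list(NULL, "a"))
  cov2 <- matrix(100L, 2, 1, dimnames = list(NULL, "a"))
  gs2 <- global_methylation_summary(make_probe_set(meth2, cov2),
                                    list(g = "a"))
  expect_equal(gs2$mean_pct, 50)
  empty <- methtile:::subset_probe_set(make_probe_set(meth2, cov2),
                                       integer(0))
  expect_error(global_methylation_summary(empty, list(g = "a")),
               "no probes")
})

test_that("treated-WT vs vehicle-WT recovers the simulated global shift", {
  pipe <- default_pipe()
  truth <- pipe$sim$truth
  bg <- truth$windows$probe_id[truth$windows$role == "background"]
  ps <- pipe$pset
  idx <- ps$probes$probe_id %in% bg
  gm <- global_methylation_summary(
    methtile:::subset_probe_set(ps, which(idx)),
    list(WT_vehicle = pipe$arm_samples$vehicle$wt,
         WT_IL1B = pipe$arm_samples$IL1B$wt))
  shift <- gm$mean_pct[gm$group == "WT_IL1B"] -
    gm$mean_pct[gm$group == "WT_vehicle"]
  expect_lt(abs(shift - pipe$sim$config$wt_il1b_global_delta), 2)
})
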