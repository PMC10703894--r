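# TF binding-site methylation: per-peak probes, summary statistics against
# brute-force enumeration, the coverage-sufficiency filter, ranking, and
# gene linkage.

# cpg_matrix with one CpG per peak and exact per-sample percentages
tf_fixture <- function(pct_wt, pct_ko) {
  n <- length(pct_wt)
  pos <- seq(100L, by = 1000L, length.out = n)
  samples <- c("wt1", "ko1")
  meth <- cbind(wt1 = as.integer(pct_wt), ko1 = as.integer(pct_ko))
  cov <- matrix(100L, n, 2, dimnames = list(NULL, samples))
  cpg <- methtile:::new_cpg_matrix(rep("c1", n), pos, meth, cov, samples)
  peaks <- data.frame(chrom = "c1", start = pos - 10L, end = pos + 10L,
                      name = sprintf("TF_peak%02d", seq_len(n)),
                      score = NA_real_, strand = NA_character_,
                      stringsAsFactors = FALSE)
  build_tf_probes(list(TF = peaks), cpg)$TF
}

test_that("summary statistics equal brute-force enumeration", {
  tfp <- tf_fixture(pct_wt = c(50, 50, 50, 50),
                    pct_ko = c(70, 55, 49, 53))  # deltas +20 +5 -1 +3
  res <- tf_meth_difference(tfp, "wt1", "ko1", genome_mean_delta = 0,
                            tf_name = "TF", min_probes = 2)
  expect_equal(res$summary$pct_sites_higher_in_KO, 75)
  expect_equal(res$summary$mean_delta_pp, 6.75)
  expect_equal(res$summary$excess_delta_pp, 6.75)
  expect_equal(res$sites$delta_pp, c(20, 5, -1, 3))
  # brute force recount
  expect_equal(res$summary$pct_sites_higher_in_KO,
               100 * sum(res$sites$delta_pp > 0) / nrow(res$sites))
})

test_that("zero differences count as not higher and excess offsets the reference", {
  tfp <- tf_fixture(pct_wt = c(40, 60), pct_ko = c(40, 60))
  res <- tf_meth_difference(tfp, "wt1", "ko1", genome_mean_delta = 7,
                            min_probes = 1)
  expect_equal(res$summary$pct_sites_higher_in_KO, 0)
  expect_equal(res$summary$excess_delta_pp, -7)
})

test_that("peaks without CpGs stay uncovered and the probe count is exact", {
  cpg <- methtile:::new_cpg_matrix(
    "c1", 100L, matrix(5L, 1, 1, dimnames = list(NULL, "s1")),
    matrix(10L, 1, 1, dimnames = list(NULL, "s1")), "s1")
  peaks <- data.frame(chrom = "c1", start = c(90L, 5000L),
                      end = c(110L, 5100L), name = c("with", "without"),
                      score = NA_real_, strand = NA_character_)
  tfp <- build_tf_probes(list(TF = peaks), cpg)$TF
  expect_equal(nrow(tfp$peaks), 2L)
  expect_equal(unname(tfp$covered), c(TRUE, FALSE))
})

test_that("the coverage-sufficiency filter is strict and TFs are independent", {
  tfp <- tf_fixture(pct_wt = rep(50, 5), pct_ko = rep(60, 5))
  at <- tf_meth_difference(tfp, "wt1", "ko1", 0, min_probes = 5)
  expect_false(at$summary$included)  # 5 covered is not > 5
  over <- tf_meth_difference(tfp, "wt1", "ko1", 0, min_probes = 4)
  expect_true(over$summary$included)

  # excluding one TF leaves the other's summary untouched
  cpgm <- small_pipe()$cpg
  peaks <- lapply(small_pipe()$sim$truth$tf_peaks, identity)
  probes_all <- build_tf_probes(peaks, cpgm)
  gs <- small_pipe()$arm_samples$vehicle
  full <- tf_meth_analysis(probes_all, gs$wt, gs$ko, 0, min_probes = 5)
  solo <- tf_meth_analysis(probes_all["TfB"], gs$wt, gs$ko, 0, min_probes = 5)
  expect_equal(full$summary[full$summary$tf_name == "TfB", ],
               solo$summary, ignore_attr = TRUE)
})

test_that("TF ranking is by mean increase with lexicographic ties", {
  s <- data.frame(tf_name = c("Zeb", "Abc", "Mid"),
                  n_probes_covered = 200, mean_delta_pp = c(7, 9, 7),
                  genome_mean_delta_pp = 0, excess_delta_pp = c(7, 9, 7),
                  pct_sites_higher_in_KO = 50, included = TRUE,
                  stringsAsFactors = FALSE)
  top2 <- rank_tfs(s, k = 2)
  expect_equal(top2$tf_name, c("Abc", "Mid"))
  expect_warning(all3 <- rank_tfs(s, k = 10), "3 included")
  expect_equal(nrow(all3), 3L)
})

test_that("gene linkage keeps only top downregulated genes near significant sites", {
  sites <- data.frame(name = c("sA", "sB"), chrom = "c1",
                      start = c(1000L, 90000L), end = c(1100L, 90100L),
                      delta_pp = c(25, 25), pvalue = c(0.001, 0.5),
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("near", "far", "near_ns"), chrom = "c1",
                      start = c(2000L, 50000L, 91000L),
                      end = c(3000L, 51000L, 92000L), strand = "+")
  de <- data.frame(gene_id = c("near", "far", "near_ns", "up"),
                   log2fc = c(-2, -1, -1.5, 2),
                   pvalue = c(1e-5, 1e-4, 1e-4, 1e-6))
  out <- link_downregulated_genes(sites, de, genes, top_n = 3)
  expect_equal(out$gene_id, "near")  # sB not significant; far too distant
  expect_equal(out$site, "sA")
  expect_equal(out$distance, 900L)

  de_up <- de[de$log2fc > 0, ]
  expect_warning(none <- link_downregulated_genes(sites, de_up, genes),
                 "no downregulated")
  expect_equal(nrow(none), 0L)
})

test_that("the planted hyper-TF recovers its excess shift on the small study", {
  pipe <- small_pipe()
  s <- pipe$tf$vehicle$summary
  hyper <- s[s$tf_name == "TfA", ]
  bg <- s[s$tf_name == "TfB", ]
  expect_lt(abs(hyper$mean_delta_pp - pipe$sim$config$tf_ko_delta), 5)
  expect_lt(abs(bg$mean_delta_pp), 5)
  expect_equal(hyper$genome_mean_delta_pp, bg$genome_mean_delta_pp)
})
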