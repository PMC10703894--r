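# DE ranking metric, signature extraction, and the preranked enrichment
# score against brute-force and fgsea oracles.

test_that("the ranking metric is the signed -log10 p-value", {
  expect_equal(rank_metric(2, 0.01), 2)
  expect_equal(rank_metric(-1.5, 0.1), -1)
  expect_equal(rank_metric(3, 1), 0)
  expect_equal(rank_metric(0, 0.001), 0)
  expect_warning(m <- rank_metric(1, 0), "floored")
  expect_equal(m, 300)
})

test_that("ranked lists are strictly ordered with deterministic ties", {
  de <- data.frame(gene_id = c("b", "a", "c"), log2fc = c(1, 1, -1),
                   pvalue = c(0.1, 0.1, 0.01))
  r <- rank_genes(de)
  expect_equal(r$gene_id, c("a", "b", "c"))  # tie broken by gene id
  expect_equal(r$metric, c(1, 1, -2))
})

test_that("top signatures filter by sign and break ties by effect size", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(2, 0.5, -1, 3),
                   pvalue = c(0.01, 0.01, 0.001, 0.5))
  expect_equal(top_signature(de, n = 2, direction = "up"), c("g1", "g2"))
  expect_warning(up <- top_signature(de, n = 100, direction = "up"),
                 "3 up-regulated")
  expect_equal(up, c("g1", "g2", "g4"))
  expect_equal(top_signature(de, n = 1, direction = "down"), "g3")
})

test_that("the planted downregulated signature is recovered exactly", {
  sim <- small_sim()
  de <- read_de_table(sim$paths$de_table)
  sig <- top_signature(de, n = length(sim$truth$target_genes),
                       direction = "down")
  expect_setequal(sig, sim$truth$target_genes)
})

test_that("extreme gene sets give the boundary enrichment scores", {
  de <- data.frame(gene_id = sprintf("g%03d", 1:50),
                   log2fc = seq(2, -2, length.out = 50),
                   pvalue = seq(0.001, 0.9, length.out = 50))
  r <- rank_genes(de)
  top <- preranked_es(r, r$gene_id[1], n_perm = 10, seed = 1)
  expect_equal(top$es, 1)
  all_genes <- preranked_es(r, r$gene_id, n_perm = 10, seed = 1)
  expect_equal(all_genes$es, 1)
  expect_error(preranked_es(r, "absent_gene"), "disjoint")
})

test_that("the enrichment score matches brute force on random fixtures", {
  set.seed(77)
  for (rep in 1:50) {
    N <- sample(50:500, 1)
    de <- data.frame(gene_id = sprintf("g%04d", 1:N),
                     log2fc = rnorm(N), pvalue = runif(N))
    r <- rank_genes(de)
    set_size <- sample(3:min(30, N - 1), 1)
    s <- sample(de$gene_id, set_size)
    es <- preranked_es(r, s, n_perm = 2, seed = 5)$es
    expect_equal(es, brute_es(r$metric, r$gene_id %in% s),
                 tolerance = 1e-12)
    expect_gte(es, -1)
    expect_lte(es, 1)
  }
})

test_that("the enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(88)
  for (rep in 1:10) {
    N <- 200
    stats <- sort(rnorm(N), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", 1:N)
    r <- structure(data.frame(gene_id = names(stats), metric = stats,
                              stringsAsFactors = FALSE),
                   class = c("ranked_genes", "data.frame"))
    idx <- sort(sample(N, 15))
    es <- preranked_es(r, names(stats)[idx], n_perm = 2, seed = 1)$es
    expect_equal(es, fgsea::calcGseaStat(stats, idx, gseaParam = 1),
                 tolerance = 1e-12)
  }
})

test_that("negating and reversing the list negates the score", {
  set.seed(31)
  de <- data.frame(gene_id = sprintf("g%03d", 1:100), log2fc = rnorm(100),
                   pvalue = runif(100))
  r <- rank_genes(de)
  s <- sample(de$gene_id, 12)
  rev_r <- structure(data.frame(gene_id = rev(r$gene_id),
                                metric = rev(-r$metric),
                                stringsAsFactors = FALSE),
                     class = c("ranked_genes", "data.frame"))
  expect_equal(preranked_es(r, s, n_perm = 2, seed = 1)$es,
               -preranked_es(rev_r, s, n_perm = 2, seed = 1)$es)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  de <- data.frame(gene_id = sprintf("g%03d", 1:150), log2fc = rnorm(150),
                   pvalue = runif(150))
  r <- rank_genes(de)
  s <- de$gene_id[sample.int(150, 10)]
  a <- preranked_es(r, s, n_perm = 500, seed = 123)
  b <- preranked_es(r, s, n_perm = 500, seed = 123)
  expect_identical(a$pvalue, b$pvalue)
  expect_identical(a$null_es, b$null_es)
  expect_gt(a$pvalue, 0)
  expect_lte(a$pvalue, 1)
})

test_that("GMT files round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(setA = c("g1", "g2"), setB = c("g3"))
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
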