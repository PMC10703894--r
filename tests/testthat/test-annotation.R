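# Enhancer classification rules, lineage exclusivity, element DMR
# fractions and gene proximity.

iv <- function(chrom, start, end, name = NA, score = NA) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, score = as.numeric(score), strand = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("presence-mode enhancer rules cover every combination", {
  k27 <- iv("c1", c(100, 300, 500, 700, 900), c(200, 400, 600, 800, 1000),
            name = c("prom_ov", "good", "me3", "no_me1", "me3_and_prom"))
  me1 <- iv("c1", c(100, 300, 500, 900), c(200, 400, 600, 1000))
  me3 <- iv("c1", c(500, 900), c(600, 1000))
  prom <- iv("c1", c(150, 950), c(160, 960))
  cl <- classify_enhancers(k27, me1, me3, prom)
  expect_equal(cl$enhancer, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cl$promoter_overlap, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("score-ratio mode applies the threshold on summed scores", {
  k27 <- iv("c1", 100, 200, name = "pk")
  me1 <- iv("c1", 100, 200, score = 2.0)
  me3 <- iv("c1", 100, 200, score = 4.0)
  none <- iv("c1", 1, 2)[0, ]
  cl <- classify_enhancers(k27, me1, me3, none, mode = "score_ratio")
  expect_false(cl$enhancer)  # ratio 0.5 < 1

  cl2 <- classify_enhancers(k27, me1, me1, none, mode = "score_ratio")
  expect_false(cl2$enhancer)  # equal scores: ratio not strictly above 1

  cl3 <- classify_enhancers(k27, me1, none, none, mode = "score_ratio")
  expect_true(cl3$enhancer)   # me3 absent: eps keeps the ratio finite

  expect_equal(nrow(classify_enhancers(none, me1, me3, none)), 0L)
})

test_that("probes are labelled by the one-and-only-one state rule", {
  probes <- data.frame(probe_id = c("pA", "pB", "pC"), chrom = "c1",
                       start = c(0L, 1000L, 2000L),
                       end = c(500L, 1500L, 2500L))
  enh <- list(HSC = iv("c1", c(100, 1100), c(200, 1200)),
              CMP = iv("c1", 1100, 1300))
  lab <- assign_state_specific_probes(probes, enh)
  expect_equal(lab$state, c("HSC", "multi", "none"))
})

test_that("state labels on the simulated study match the truth exactly", {
  pipe <- small_pipe()
  truth <- pipe$sim$truth
  # classifier output equals the truth enhancer set per state
  for (st in names(pipe$enhancer_sets)) {
    want <- sort(sub("^enh", "k27", truth$enhancers$name[
      truth$enhancers$state == st]))
    expect_equal(sort(pipe$enhancer_sets[[st]]$name), want)
  }
  # every enhancer-role probe carries its own state, never multi
  layout <- truth$windows
  lab <- pipe$probe_states
  enh_rows <- layout[layout$role == "enhancer", ]
  got <- lab$state[match(enh_rows$probe_id, lab$probe_id)]
  expect_equal(got, enh_rows$state)
  # background-role probes overlap no enhancer
  bg_rows <- layout$probe_id[layout$role == "background" & !layout$buffer]
  expect_true(all(lab$state[match(bg_rows, lab$probe_id)] == "none"))
})

test_that("element DMR fractions use overlapping tested probes as denominator", {
  calls <- data.frame(probe_id = sprintf("p%02d", 1:10), chrom = "c1",
                      start = seq(0, 900, 100), end = seq(50, 950, 100),
                      delta_pp = c(rep(30, 3), rep(-30, 1), rep(0, 6)),
                      pvalue = 0.001, qvalue = 0.001,
                      direction = c(rep("hyper", 3), "hypo", rep("hypo", 6)),
                      significant = c(rep(TRUE, 4), rep(FALSE, 6)),
                      stringsAsFactors = FALSE)
  sets <- list(all = iv("c1", 0, 1000), off = iv("c2", 0, 1000))
  fr <- element_dmr_fractions(calls, sets)
  expect_equal(fr$pct_hyper, c(30, NA))
  expect_equal(fr$pct_hypo, c(10, NA))
  expect_true(all(fr$pct_hyper + fr$pct_hypo <= 100, na.rm = TRUE))
})

test_that("gene linkage respects the distance boundary exactly", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      start = c(10000L, 50000L), end = c(12000L, 52000L),
                      strand = c("+", "-"))
  q <- iv("c1", c(7001, 6999, 10500), c(8001, 7999, 10600),
          name = c("gap1999", "gap2001", "inside"))
  links <- link_genes(q, genes, max_distance_bp = 2000)
  expect_setequal(links$interval, c("gap1999", "inside"))
  expect_equal(links$distance[links$interval == "inside"], 0L)
  expect_equal(links$distance[links$interval == "gap1999"], 1999L)
})

test_that("interval-gene relations are promoter, intragenic or distal", {
  gene <- data.frame(gene_id = "g", chrom = "c1", start = 5000L,
                     end = 9000L, strand = "+")
  x <- iv("c1", c(4500, 6000, 20000), c(4600, 6100, 20100))
  expect_equal(classify_gene_relation(x, gene),
               c("promoter", "intragenic", "distal"))
  gm <- data.frame(gene_id = "g", chrom = "c1", start = 5000L, end = 9000L,
                   strand = "-")
  xm <- iv("c1", c(9100, 6000, 3000), c(9200, 6100, 3100))
  expect_equal(classify_gene_relation(xm, gm),
               c("promoter", "intragenic", "distal"))
})

test_that("hyper-DMR fraction at planted enhancers exceeds background", {
  pipe <- default_pipe()
  truth <- pipe$sim$truth
  calls <- pipe$dmr$vehicle
  enh_set <- truth$enhancers
  bg <- truth$windows[truth$windows$role == "background", ]
  fr <- element_dmr_fractions(calls, list(
    enhancers = enh_set,
    background = bg[, c("chrom", "start", "end")]))
  expect_gt(fr$pct_hyper[fr$element == "enhancers"],
            fr$pct_hyper[fr$element == "background"])
})
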