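# methtile

Tiled CpG probe analysis of whole-genome bisulfite sequencing (WGBS),
with regulatory annotation and a fully synthetic, truth-tracked test
bed.

`methtile` is aimed at epigenomics analysts who work with WGBS of small
replicate designs — e.g. knockout vs wild-type animals with and without
a treatment — and who want the classic windowed-probe workflow as
scriptable, tested R functions:

1. **Probe tiling & quantification** — partition each chromosome into
   consecutive windows of exactly 50 CpGs; quantify each probe per
   sample by pooled counts, `100·Σmeth / Σ(meth+unmeth)`; keep a probe
   only if it has ≥ 10 covered CpGs in every sample of the comparison.
2. **DMR calling** — per probe, a binomial GLM with logit link on the
   per-sample `(meth, unmeth)` totals with a group indicator; p-value
   from the likelihood-ratio test against the intercept-only model
   (χ², 1 df); Benjamini–Hochberg correction; a probe is a DMR when
   `q < 0.05` **and** `|Δ| ≥ 10` percentage points (Δ = KO − WT group
   mean of per-sample percentages). Complete separation is handled with
   a flagged Haldane 0.5 pseudo-count.
3. **Enhancer classification** — an H3K27ac peak is an enhancer when it
   overlaps no promoter and its H3K4me1 evidence dominates H3K4me3
   (peak presence by default, or a score ratio); probes overlapping
   enhancers of exactly one cell state are lineage-specific, the rest
   are `multi`/`none`.
4. **TF binding-site methylation** — one probe per ChIP peak; per-TF
   mean Δ, excess over the genome-wide mean Δ, and the percentage of
   sites with higher methylation in KO; TFs with ≤ 100 covered probes
   are excluded.
5. **Motif enrichment** — log-odds PWM scanning on both strands and an
   upper-tail hypergeometric test of hit-bearing probes (significant
   DMRs vs all other tested probes).
6. **DE signatures** — genes ranked by `sign(log2FC)·(−log10 p)`, top-N
   signature extraction, and the classic preranked enrichment score
   (weighted KS running sum) with a gene-label permutation null.
7. **Synthetic methylome** — a seed-deterministic generator that writes
   a genome FASTA, bismark-style coverage files for a 2×2
   genotype/treatment design (4 replicates per group), histone and TF
   peak BEDs, annotation, and a DE table, together with a truth table
   of every planted feature.

## Worked example

Simulate the default study (2 Mb genome, ~800 fifty-CpG probes, planted
+30 pp enhancer hypermethylation in the KO, a +25 pp shift at one TF's
binding sites, −8 pp global reduction in IL1B-treated WT) and run the
whole pipeline:

```r
library(methtile)

pipe <- run_methylome_pipeline(tempfile("demo"), sim_config(seed = 42))

lapply(pipe$dmr, dmr_counts)
#> $vehicle
#> hyper  hypo
#>   260     0
#> $IL1B
#> hyper  hypo
#>   369     0

pipe$global_meth
#>        group n_probes mean_pct       sem
#> 1 WT_vehicle      800 59.87720 0.7816700
#> 2    WT_IL1B      800 51.85286 0.7859749
#> 3 KO_vehicle      800 69.24369 0.3112962
#> 4    KO_IL1B      800 69.20641 0.3119361

pipe$tf$vehicle$summary[1, c("tf_name", "mean_delta_pp",
                             "excess_delta_pp", "pct_sites_higher_in_KO")]
#>   tf_name mean_delta_pp excess_delta_pp pct_sites_higher_in_KO
#> 1    Spi1      25.10242        15.73593                    100

head(pipe$motif$vehicle, 1)
#>      motif  k   n  K   N       pvalue       qvalue
#> 1 AP1_like 79 260 83 800 1.502521e-37 4.507564e-37
```

Reading the output: the vehicle arm calls 260 hypermethylated DMRs —
the 200 planted enhancer probes plus the 60 TF-shift windows — and none
hypomethylated. The global means show the −8 pp IL1B-induced reduction
in WT (59.9 → 51.9) while the KO resists it (69.2 → 69.2), which is why
the treated arm calls *more* hyper-DMRs (369): the KO−WT gap widens
genome-wide. The planted TF recovers its +25 pp shift (mean Δ = 25.1),
an excess of +15.7 over the genome-wide mean Δ of +9.4, with 100% of
its sites more methylated in the KO; and the planted AP-1-like motif is
found in 79 of the 260 hyper-DMR probes against 4 background
occurrences (q ≈ 5·10⁻³⁷).

Every stage is also callable on its own (`read_coverage`,
`merge_coverage`, `tile_probes`, `quantify_probes`,
`apply_coverage_filter`, `dmr_test`, `call_dmrs`, `classify_enhancers`,
`assign_state_specific_probes`, `element_dmr_fractions`,
`build_tf_probes`, `tf_meth_analysis`, `link_downregulated_genes`,
`scan_sequence`, `hypergeometric_enrichment`, `enrich_dmrs`,
`rank_genes`, `top_signature`, `preranked_es`, …) on real coverage
files, BEDs and DE tables in the same dialects.

## Documentation

The methods vignette (`vignettes/methtile-methods.Rmd`) describes the
statistical models, the synthetic-data design and its limitations, and
every tunable parameter with its default and rationale.
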