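---
title: "methtile: models, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methtile: models, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`methtile` analyses whole-genome bisulfite sequencing (WGBS) at the level
of *windowed CpG probes*: the genome is partitioned into consecutive
windows of exactly 50 CpGs, each probe is quantified per sample by pooled
read counts, and a binomial logistic regression tests each probe for
differential methylation between two groups (here, a knockout/wild-type
contrast within each treatment arm of a 2x2 genotype-by-treatment
design). Downstream layers interpret the probe calls against regulatory
annotation: histone-mark-defined enhancers with lineage-exclusive probe
assignment, transcription-factor (TF) ChIP binding sites scored for
methylation differences, known-motif enrichment inside differentially
methylated regions (DMRs), and a preranked gene-set enrichment score over
a differential-expression (DE) ranking. A synthetic methylome generator
produces every input with a known truth table so the whole chain is
testable end to end without external data.

# The probe model

**Tiling.** Windows step by exactly `window_cpgs` (default 50) CpGs, do
not overlap, never span chromosomes, and a trailing remainder shorter
than a full window is discarded. Whether the original windowed-probe
approach steps or slides is not fully standardised across tools;
non-overlapping stepping is the assumption here, is configurable, and
keeps probes statistically independent at the count level.

**Quantification.** A probe's methylation in a sample is the pooled-count
percentage `100 * sum(meth) / sum(meth + unmeth)` over its member CpGs.
Pooling weights CpGs by coverage, matching the count-based test below,
and is invariant to how reads are distributed among the probe's CpGs at
fixed totals. Probes with zero coverage in a sample are *undefined*
(`NA`), never 0.

**Coverage filter.** A probe enters a comparison only if it has at least
`min_covered_cpgs` (default 10) CpGs with at least one read in *every*
sample of that comparison. The filter is applied per comparison, so the
vehicle-arm and treated-arm contrasts may test slightly different probe
sets. Raising the threshold can only shrink the tested set (a property
the tests assert).

# The differential test

Each probe is tested with a binomial generalised linear model with logit
link on the per-sample pooled `(methylated, unmethylated)` totals and a
single group indicator. The p-value is a likelihood-ratio test against
the intercept-only model, referred to chi-square with 1 degree of
freedom. Replicates enter as separate binomial observations; there is no
explicit overdispersion term. That is a deliberate, documented
limitation: between-animal variance inflates the null deviance of the
one-parameter model rather than being absorbed by a dispersion
parameter, which is why significance is paired with an effect-size
threshold (below) rather than trusted alone.

The reported effect `delta_pp` is the difference of group means of the
per-sample probe percentages (each animal weighted equally), in
percentage points, oriented knockout minus wild type.

**Complete separation** (one group at exactly 0% or 100% in all of its
samples) makes the logistic MLE diverge. Such probes receive a Haldane
pseudo-count of 0.5 added to both counts of *every* sample, are refitted
and flagged. This was chosen over Firth penalisation because it is
simple, probe-local and easy to verify.

**Significance.** Benjamini-Hochberg correction is applied over all
tested probes of one comparison; a probe is a DMR when `q < alpha`
(default 0.05) *and* `|delta_pp| >= min_delta` (default 10 percentage
points). A `correction = "raw_p"` switch reproduces the uncorrected
`p < 0.05` rule; the corrected rule is the default because headline DMR
counts should be FDR-controlled. Direction is `hyper` for positive
deltas (higher in knockout), `hypo` otherwise.

**Calibration.** On simulated null probes (equal group probabilities,
4 vs 4, negative-binomial coverage with mean 20 per CpG, no
replicate-level jitter) the fraction of raw likelihood-ratio p-values
below 0.05 sits near the nominal level (the acceptance suite requires
[0.03, 0.07] over 2,000 probes). With one sample per group the test
reduces to the pooled 2x2 contrast, where it agrees with the Pearson
chi-square within a few percent relative error at cell counts of 20 or
more, and its deviance matches a direct log-likelihood evaluation at the
fitted proportions to numerical precision.

# Regulatory annotation

**Enhancers.** For one cell state, an H3K27ac peak is called an enhancer
when it overlaps no known promoter element and its H3K4me1 evidence
dominates H3K4me3. Because peak files may or may not carry usable
scores, two modes are provided: *presence* (default; at least one
overlapping H3K4me1 peak and no H3K4me3 peak) and *score_ratio*
(summed overlapping H3K4me1 score over summed H3K4me3 score strictly
above a threshold, default 1, with an epsilon of 1e-9 guarding the
division). The ratio formulation in the underlying literature was
computed from re-aligned reads, which is out of scope here; the
presence mode is the faithful peak-level reduction of the same idea.

**Lineage exclusivity.** A probe overlapping enhancers of exactly one
state is labelled with that state; two or more states give `multi`
(excluded from lineage-specific analyses), none gives `none`. The set of
states is configuration, not hard-coded, because different data sets
define different progenitor panels.

**Element overlap fractions.** For each element class (lineage
enhancers, promoters, CpG islands, gene bodies) the denominator is the
set of tested probes overlapping the element by at least 1 bp, and the
numerators are the significant hyper-/hypomethylated probes among them.
Elements with no overlapping tested probe are *undefined*, not 0%.
Probe-element overlap deliberately requires only a single base.

**Gene proximity.** Distance between an interval and a gene is 0 when
they overlap and the gap between closest ends otherwise; genes within
`max_distance_bp` (2,000 by default, 5,000 for looser pathway-style
linkage) are linked, sorted by distance then gene id. Promoters default
to TSS-1000..TSS+500, strand-aware, when not supplied as an input BED.

# TF binding-site methylation

TF probes are one per ChIP peak interval (not 50-CpG windows), pooled
over the CpGs inside the peak; a peak with no CpGs is retained but
permanently uncovered. A TF is *included* only when it has strictly more
than `min_probes` (default 100) covered probes — a peak is covered when
every sample of the comparison has at least one covered CpG in it.
Summaries per TF: the mean per-peak difference, the *excess* over the
genome-wide mean difference of all tested 50-CpG probes of the same
comparison (one shared reference per comparison), and the percentage of
sites with strictly higher methylation in the knockout (a zero
difference counts as not higher). The genome reference is probe-level
rather than CpG-level for consistency with the tested universe; this is
a documented choice.

Linkage to expression takes the `top_n` most significantly
downregulated genes (negative fold change, ascending p, deterministic
ties) and intersects them with genes within the linkage distance of any
significantly hypermethylated site (positive delta, raw `p < 0.05`; the
raw-p rule is used only in this linkage step). Both 100 and 150 are
sensible values of `top_n` and it is exposed as a parameter.

# Motif enrichment

The scanner scores every offset of a sequence, on both strands, with the
log2-odds of a position weight matrix (PWM) against background base
frequencies (uniform 0.25 by default); a hit scores at least
`threshold_fraction` (default 0.8) of the maximum achievable score, and
`N` bases contribute zero log-odds. Enrichment is an upper-tail
hypergeometric test of hit-bearing probes: foreground = significant DMRs
of one direction, background = all other tested probes of the same
comparison (a matched-universe design mirroring region-based known-motif
tools), with a probe counting once regardless of hit multiplicity
(ZOOPS counting). De-novo motif discovery is explicitly out of scope,
and no scanner parameter is claimed to reproduce any external tool
numerically.

# DE ranking and enrichment score

Genes are ranked by `sign(log2FC) * -log10(p)` with the p-value floored
at 1e-300 and deterministic tie-breaking, and signatures are the top-N
genes of one fold-change sign (ascending p, ties by larger effect then
gene id). The preranked enrichment score is the classic weighted
Kolmogorov-Smirnov running sum (hit increments `|metric|^w` normalised
by the in-set total, default `w = 1`; miss decrements `1/(N - |S|)`),
with the extremum of largest absolute value (first such index on exact
ties). The permutation null resamples size-matched *gene-label* sets —
phenotype permutation needs the expression matrix, which a ranked list
does not carry — and the p-value is the add-one-smoothed fraction of
matching-sign null scores at least as extreme, so a finite permutation
count can never report exactly zero. The normalised score divides by the
mean absolute null score of matching sign. Permutation count and weight
exponent are configuration (defaults 1,000 and 1).

# The synthetic methylome

The generator emulates the structure of a 2x2 genotype-by-treatment WGBS
study with 4 replicates per group on a small genome (default 2 Mb over
2 chromosomes):

* **Sequence and CpGs.** Random sequence is thinned to a target CpG
  density. The default density (0.02 of dinucleotides) is deliberately
  CpG-condensed relative to a mammalian genome-wide average so that a
  2 Mb genome yields ~800 full 50-CpG probes — enough to host all
  planted feature classes and still leave several hundred null probes.
  The synthetic genome is therefore best thought of as a genome in
  which every window is already CpG-informative.
* **Feature placement is probe-aligned.** The generator tiles its own
  genome with the same windowing rule as the analysis and assigns whole
  windows to features: enhancers span 2 consecutive windows (100
  enhancers over 4 states by default, giving 200 planted DMR probes),
  selected TF windows carry the planted TF shift, and decoy windows host
  H3K27ac peaks that each violate exactly one enhancer rule (H3K4me3
  present, promoter overlap, or H3K4me1 absent). Windows adjacent to
  enhancers are left as unused buffer so promoters and genes placed
  later can never bleed into an enhancer and corrupt the truth labels.
* **Methylation model.** Enhancers sit at a hypomethylated base level
  (0.25) against a 0.75 background; TF-peak windows sit at 0.40 so the
  planted +25 pp knockout shift cannot clamp at 1. The knockout adds
  +30 pp at enhancers and +25 pp at hyper-TF windows; treated wild-type
  samples are shifted -8 pp genome-wide while the knockout resists the
  reduction. All probabilities are clamped to [0, 1] after shifts.
* **Counts.** Coverage per CpG and sample is negative binomial (mean 20,
  dispersion 0.2; Poisson at dispersion 0) to reflect WGBS
  overdispersion; methylated counts are binomial. Replicate-level
  variance comes from a per-sample, per-window Beta jitter around the
  group probability with concentration `kappa = 200` — a standard
  deviation of roughly 3 percentage points at p = 0.75, a realistic
  between-animal spread at probe scale. All CpGs of a window share one
  jitter draw per sample, which is what makes the jitter visible to a
  probe-level test. Calibration studies of the test disable the jitter,
  matching their definition of exactly equal group probabilities.
* **Motifs.** An AP-1-like consensus (`ATGACTCATT`) is embedded in 80%
  of enhancers. The consensus contains no CG dinucleotide and instances
  are only planted at offsets where the replacement can neither create
  nor destroy a CG, so the CpG position list of the final sequence is
  exact and feature/window alignment survives planting. Two decoy PWMs
  are provided that are never planted.
* **Genes and DE.** Target genes are placed within 2 kb of hyper-TF
  peaks and given strongly negative fold changes with tiny p-values;
  background genes get null DE statistics. Promoters are strand-aware
  TSS-1000..TSS+500 windows; some decoy H3K27ac peaks carry their own
  overlapping promoter annotation.
* **Coordinates and dialects.** Everything is 0-based half-open
  internally; the bismark-style coverage writer converts to 1-based
  inclusive positions and emits *all* CpGs including uncovered ones so
  that the per-sample files share one position universe and round-trip
  losslessly (real bismark output omits uncovered rows; the reader
  accepts both). CpGs are strand-merged: one record per forward-strand
  CG, as in non-strand-specific processing.

**What the simulator does not model.** Read-level artefacts (bisulfite
conversion errors, mapping bias, PCR duplicates), SNP-aware methylation,
non-CpG contexts, spatial autocorrelation beyond the window scale,
realistic chromatin-state-dependent CpG density, and any coupling
between expression and methylation beyond the planted target genes.
Passing tests on synthetic data therefore demonstrate the correctness of
the *computational chain* under its stated statistical model, not the
biological fidelity of any particular call set on real data.

# Problem sizes and determinism

The reference study conditions (the defaults, seed 42 in the test suite)
are a 2 Mb genome, ~40,000 CpGs, 800 probes, 16 samples, 4 TFs with 120
peaks each, and 200 genes; a full pipeline run takes on the order of a
minute on a single core. The test suite and the acceptance script use
these sizes directly. Every random step is seed-determined; running the
pipeline twice with the same configuration produces byte-identical
result files, which the suite asserts file by file.

# Known limitations

* No overdispersion term in the probe test: with strong replicate-level
  jitter the raw p-values are anticonservative, which is mitigated but
  not removed by the paired effect-size threshold. A beta-binomial
  model would be the natural extension and is intentionally out of
  scope.
* Adjacent significant probes are not merged into larger DMRs.
* The enhancer score-ratio mode depends on the meaning of the input
  BED scores, which the package cannot verify.
* The ES permutation null is gene-label based, not phenotype based.
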