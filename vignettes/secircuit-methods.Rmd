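---
title: "Methods: super-enhancer calling, core regulatory circuitry, and occupancy-stratified response"
author: "secircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer calling and core regulatory circuitry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures the package implements,
the assumptions behind them, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where conventions in the field are not fully pinned
down.

## Coordinate model and signal quantification

All coordinates are 0-based, half-open `[start, end)` (BED convention).
GTF input (1-based, closed) is converted at the reader boundary; nothing
downstream ever reasons about 1-based coordinates. Signal tracks are
per-chromosome sorted, disjoint, non-negative piecewise-constant coverage
(bedGraph semantics); gaps read as zero and chromosomes absent from a track
quantify to zero rather than erroring, because sparse tracks are normal.
Signal is interpreted as density per base, so the area over a region is
`value × overlap width` summed across overlapped segments; areas are
computed from per-chromosome cumulative sums, which makes region
quantification O(log n) per query and exactly additive over partitions.

## Super-enhancer calling

The caller follows the rank-ordering recipe used for H3K27ac-defined
super-enhancers:

1. **TSS exclusion** (`tss_pad = 1250` bases): bases within ±1250 bp of any
   TSS are subtracted from peaks before stitching, so promoter signal does
   not inflate enhancer ranks. A peak straddling an exclusion zone is split
   into its surviving parts; the original extent is retained for
   constituent reporting only.
2. **Stitching** (`stitch_distance = 12500` bases): peaks whose gap is at
   most the stitching distance merge transitively. 12.5 kb is the classic
   ROSE default; the method itself only requires *some* clustering scale
   and the parameter is exposed.
3. **Scoring**: net signal is `max(chip − input, 0)`, quantified over the
   union of (TSS-excluded) constituents so excluded bases contribute
   nothing. Ties in net signal are broken by wider region first, then
   leftmost coordinate — an arbitrary but fixed convention that makes
   ranking deterministic. Net signals are reported at 1e-6 precision so
   tie-breaking cannot depend on the order of floating-point accumulation.
4. **Inflection cutoff**: the ascending signal-vs-rank curve is rescaled to
   the unit square and the cutoff is the *first* point whose discrete slope
   exceeds 1 — the discrete formulation of "the point where a line of
   slope 1 is tangent to the curve". Regions strictly above the cutoff
   value are SEs. Degenerate inputs (fewer than 3 regions, all-equal or
   perfectly linear signals) yield zero SEs with a warning rather than an
   error: tiny synthetic runs should fail soft.
5. **Hockey-stick normalization**: `relative_rank = rank / (n_SE + n_TE)`
   and `pct_signal = 100 × net / Σ net`, which puts samples with different
   enhancer counts and sequencing depths on comparable axes. The identities
   `relative_rank ∈ (0, 1]` and `Σ pct_signal = 100` hold by construction
   and are asserted in the test suite.
6. **Gene assignment** (`flank = 50000` bases): a region is assigned every
   gene whose TSS lies within the region ± 50 kb, with a nearest-TSS
   fallback when none does. The annotation rule behind published
   SE–gene tables is typically not fully specified; TSS-within-flank plus
   nearest-gene fallback is a common, conservative choice and both knobs
   are parameters.

**Assumptions.** Input-subtracted signal is non-negative where biology is
real; enhancer clusters are wider and hotter than singletons; a single
inflection point separates the two populations. When a sample violates the
last assumption (e.g. a continuum of enhancer strengths), the cutoff is
still well-defined but the SE/TE dichotomy is less meaningful — the full
ranked table is always returned so users are not locked into the cutoff.

## Occupancy classification

The promoter window is **strand-aware**: −1000/+200 bp around the TSS in
the direction of transcription. The convention −1000/+200 is conventionally
strand-relative even when described without strand. Categories are mutually
exclusive with precedence Promoter > Enhancer_SE > Enhancer_TE > Other
(configurable), because published genomic-distribution pie charts imply
exclusivity. Co-localization of two peak sets uses ≥ `min_bp` shared bases
with `min_bp = 1` by default — the minimum overlap behind "co-localized"
is rarely stated, so the loosest defensible definition is the default and
the parameter is exposed. "Active promoters" are approximated as promoters
of genes passing the mean FPKM > 0.5 activity filter when expression is
supplied, otherwise all promoters.

## RNA-Pol2 pausing and metagene profiles

The pausing index is the ratio of mean signal **density** over the
strand-relative TSS window to mean density over the gene body. Densities,
not raw areas, so unequal window lengths cancel. Window defaults are
TSS −50/+300 and body +300 → TES, a common traveling-ratio convention; the
windows are parameters and quantitative pausing values should only be
compared across analyses run with identical windows — orderings, not
absolute values, are the robust output. Genes shorter than the body offset
or with zero body density are flagged undefined rather than producing
infinities.

Metagene profiles average per-bin mean density over ±2500 bp of each
anchor in 25 bp bins; minus-strand anchors have their bin order reversed
so profiles align with transcription direction. Bases beyond the genome
edge quantify as zero.

## CRC reconstruction

PWM scanning is log-odds in bits against a uniform background with
pseudocount mixing
(`score = Σ log2((p + pc·bg) / ((1 + pc)·bg))`), both strands, `N` scoring
as background. The scan threshold defaults to 80% of each PWM's maximum
attainable score — a standard fraction-of-maximum rule; no absolute
threshold is defensible across motif widths. The scanning substrate is the
**full SE region sequence** rather than H3K27ac valleys: valley calling
adds a detection step whose parameters are themselves unstated, and on
desk-scale data the full span is the more reproducible choice. This is a
documented divergence from valley-based CRC mappers; the scanned window is
configurable by passing narrower regions.

A TF enters the graph only if it is SE-associated, expressed, and
**auto-regulated** (its own motif hits its own SE); a directed edge i→j
requires at least one hit of motif i in any SE assigned to TF j. Mutual
edge pairs are treated as undirected and maximal cliques enumerated
(Bron–Kerbosch with pivoting via igraph; a 25-node cap keeps enumeration
tractable and forces explicit filtering on larger candidate sets —
brute-force subset enumeration is the test oracle). Core TFs are ranked by
(1) clique membership fraction, (2) mean Pearson correlation of
log2(FPKM+1) with the TF's **clique partners**, (3) rank of the TF's own
SE. The partner-restricted correlation is deliberate: when the graph is one
planted clique plus isolated auto-regulated decoys, every node lies in
exactly one maximal clique and the membership fraction ties, while a mean
over *all* nodes dilutes the co-operative signal and, in a
treatment/control design, is confounded by the response shared across all
SE-associated genes. Correlation with the TFs a candidate actually
co-occupies cliques with is the discriminating reading of "co-operative
core TFs". All three components are reported so users can re-rank.

## Expression response statistics

Fold changes are `log2((mean_b + 1) / (mean_a + 1))` on FPKM means — a
pseudocounted ratio, not a shrunken model-based estimate. The
stratified-response conclusions this feeds are rank-based comparisons
across gene classes, which the pseudocounted ratio supports at desk scale;
negative-binomial differential-expression machinery is intentionally out of
scope. The `log2(x + 1)` convention is applied everywhere a log of
possibly-zero signal is taken (expression, SE signal matrix).

Group comparisons use rank tests implemented in the package:
Mann–Whitney/rank-sum for unpaired groups and Wilcoxon signed-rank (zeros
dropped, ties mid-ranked) for paired data. The null distribution is
computed **exactly under ties** by a generating-function dynamic program
over doubled mid-ranks — equivalent to full enumeration of all
`choose(m+n, m)` assignments or `2^n` sign patterns — for up to 25
observations per group (unpaired) or 25 non-zero differences (paired), and
by normal approximation with tie and continuity corrections beyond. The
standard library implementation abandons exactness in the presence of ties,
which is why the test is hand-implemented; the tie-free special case is
cross-checked against it in the suite. Gene-group comparisons default to
the **unpaired** variant: groups of different genes are structurally
unpaired, even where published figure legends name the signed-rank test;
`paired = TRUE` restores the literal behaviour where genuine pairing
exists.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, on
a single ~6 Mb toy chromosome divided into regular gene slots:

- **Enhancers**: 8 planted SEs built from 2–6 constituent peaks (1 kb each,
  600–1000 bp gaps — within stitching range, so stitching is actually
  exercised) against 80 singleton TEs, at amplitudes 20 vs 5
  (4:1) over truncated-Gaussian noise with sd 2 (a tenth of the SE
  amplitude). A matched pure-noise input track is produced. SE slots keep a
  minimum separation so neighbouring clusters cannot stitch together.
- **TF peaks**: each SE constituent receives a TF peak with probability
  0.9; 50 background peaks land in enhancer-free slots; a matched TF
  signal track supports TF-overload ranking.
- **Pol2**: per gene, constant body density 2 and TSS density
  `PI_true × 2` (default `PI_true = 3`) over exactly the estimator's
  windows, so noiseless tracks invert the estimator identically; optional
  noise at sd 0.3.
- **Motifs**: near-one-hot 10-mer PWMs; planted regulatory edges write the
  source TF's consensus (forward or reverse-complement) into an SE
  constituent of the target TF's cluster, with collision-avoiding retries.
- **Expression**: log2 FPKM = baseline 3 + 2·1[SE-associated] + latent
  factor (loading 1.0, giving pairwise r ≈ 0.8 among CRC TFs) + N(0, 0.5);
  treatment shifts SE-associated genes by −1; 5% of genes are silent
  (below the activity filter); 3 samples per condition.

Every simulator is a pure function of (inputs, seed); per-stage seeds are
derived from the global seed by stable hashing of stage names, so adding a
stage never perturbs earlier stages' draws. Effect sizes not fixed by the
emulated study design (expression effects, amplitudes, noise) were chosen
once as values a practitioner would call realistic for strong enhancer
biology and are recorded above; they are parameters of `sim_config()`, not
calibrated constants.

**What passing tests do and do not show.** The generator produces
piecewise-constant signal, independent Gaussian noise, disjoint genes on a
uniform-background sequence, and planted effects that exactly satisfy the
models the estimators invert. Real ChIP-seq adds fragment-length smearing,
GC and mappability bias, copy-number structure, overlapping transcription
units and motif self-similarity — none of which are emulated. Recovery of
planted structure therefore validates the *correctness of the
implementation and the internal consistency of the method chain*, not the
method's power on real data.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale: 6 Mb genomes with
200 genes, ≤ 200-peak oracle comparisons (100 random sets), 20-seed
SE-recovery and CRC-recovery experiments, 200 random graphs of ≤ 12 nodes
against 2^n clique enumeration, and 50 scanning oracles — sizes chosen so
the whole suite completes in a few minutes while every oracle remains an
exact, exhaustive check. Numerical conventions: net signals rounded to
1e-6 before ranking (tie determinism); `Σ pct_signal = 100` asserted to
1e-6; scan scores compared to 1e-9; rank-test exactness asserted to 1e-12
against enumeration.

## Known limitations

- Single-factor inflection: no support for slope-window smoothing variants
  of the SE cutoff; results can differ from implementations that smooth.
- Gene assignment ignores topological domains and expression-based target
  mapping; the ±50 kb rule is a proximity heuristic.
- The CRC edge definition is binary (≥ 1 hit); hit counts are recorded but
  not modelled.
- FPKM-based fold changes are not variance-stabilised; very low-expressed
  genes are handled only by the pseudocount and the activity filter.
- bigWig input is not supported; convert to bedGraph upstream.
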