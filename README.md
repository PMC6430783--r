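# secircuit

Super-enhancer calling and core regulatory circuitry analysis for
enhancer-centred cancer epigenomics, with a synthetic-data generator that
plants ground truth so every stage can be validated end-to-end.

## The problem

Malignant cells concentrate their transcriptional machinery on a small set
of **super-enhancers (SEs)** — clusters of enhancers with exceptionally high
aggregate H3K27ac (or transcription-factor) ChIP-seq signal. SE-associated
transcription factors that bind their own and each other's SEs form a
**core transcriptional regulatory circuitry (CRC)**: fully interconnected
feed-forward loops that stabilise the malignant expression program. This
package implements the analysis chain a regulatory-genomics study runs
downstream of alignment and peak calling:

1. **SE calling** (ROSE-style): peaks within ±1250 bp of a TSS are excluded,
   the rest are stitched when separated by ≤ 12.5 kb, stitched regions are
   ranked by input-subtracted signal *S(r) = max(chip(r) − input(r), 0)*,
   and the geometric inflection point of the rescaled rank–signal curve —
   the first discrete slope exceeding the unit diagonal — separates SEs from
   typical enhancers (TEs). The hockey-stick curve is normalized per sample:
   *relative rank = rank / (n_SE + n_TE)* and
   *% signal = 100 · S(r) / Σ S*.
2. **Occupancy classification**: peaks fall into Promoter
   (strand-aware −1000/+200 bp of TSS), Enhancer_SE, Enhancer_TE or Other,
   with promoter-occupancy combinations for factor families (e.g. BET
   proteins BRD2/3/4), TF-overloaded enhancers (the same ranking applied to
   a TF's own signal) and double-positive SE gene sets.
3. **RNA-Pol2 metrics**: pausing index *PI = density(TSS window) /
   density(gene body)* and strand-oriented metagene profiles
   (±2500 bp, 25 bp bins).
4. **CRC reconstruction**: PWM log-odds scanning (both strands, bits) of SE
   sequences, an auto-/mutual-regulation TF graph, Bron–Kerbosch maximal
   cliques, and a composite core-TF ranking (clique membership,
   clique-partner co-expression, own-SE rank).
5. **Expression response**: active-gene filtering (mean FPKM > 0.5),
   pseudocounted log2 fold changes, occupancy-stratified group comparisons
   with exact rank tests (Mann–Whitney / Wilcoxon signed-rank, exact under
   ties), and the log2 SE signal matrix for clustering.

Everything is tidyverse-native: functions take and return tibbles, results
are S3 objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate an H3K27ac landscape with 8 planted SEs against 80 typical
enhancers (4:1 amplitude, noise at a tenth of the SE amplitude), call SEs,
and check the calls against the planted truth:

```r
library(secircuit)

cfg    <- sim_config(seed = 7)
genome <- simulate_genome(cfg, sequence = FALSE)
h3k    <- simulate_h3k27ac(genome, cfg)

call <- call_superenhancers(h3k$peaks, h3k$chip, genome$genes,
                            input = h3k$input, sample_id = "toy")
call
#> <se_call> sample 'toy': 88 stitched enhancers (8 SE, 80 TE), cutoff 5992

glance(call)
#> # A tibble: 1 × 6
#>   sample_id n_enhancers  n_se  n_te cutoff_value se_pct_signal
#> 1 toy                88     8    80        5992.          58.0

head(tidy(call)[, c("rank", "net_signal", "is_se", "relative_rank",
                    "pct_signal", "nearest_gene")], 3)
#>    rank net_signal is_se relative_rank pct_signal nearest_gene
#> 1     1    121915. TRUE         0.0114      13.0  gene_132
#> 2     2    100839. TRUE         0.0227      10.7  gene_116
#> 3     3     80800. TRUE         0.0341       8.60 gene_005

se_recovery(call, h3k$truth)
#> # A tibble: 1 × 4
#>   n_called n_planted precision recall
#> 1        8         8         1      1

autoplot(call)   # hockey-stick plot with the SE population highlighted
```

The 8 planted SEs are recovered exactly; the SE population — 9% of stitched
enhancers — captures 58% of the total enhancer signal, the asymmetry the
hockey-stick plot visualises. `run_pipeline(pipeline_config(seed = 1))`
chains all six stages (simulate → call-se → annotate → pol2 → crc →
respond) on one synthetic dataset, writes every stage's files plus a log
with checksums, and returns a JSON-serialisable summary; reruns with the
same seed are byte-identical.

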