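# ffpeqc

Quality and reliability metrics for gene expression data from
formalin-fixed paraffin-embedded (FFPE) tissue.

Formalin fixation fragments and chemically modifies RNA, so FFPE-derived
expression data cannot be judged — or compared with fresh-frozen (FF)
counterparts — the way intact-RNA data are. Ribosomal-peak integrity
scores are uninformative once the rRNA peaks are gone, and FF and FFPE
arrays form separate data entities whose absolute signals must not be
compared directly. `ffpeqc` implements the indirect measures that work in
this setting, for molecular pathologists and core facilities deciding
whether archival material is usable and for analysts quantifying how much
trust FFPE-derived profiles deserve:

- **DV200** — the percentage of RNA fragments longer than 200 nt in a
  capillary electrophoresis trace,
  `DV200 = 100 · ∫_{s>200} f(s) ds / ∫ f(s) ds` (trapezoidal integration
  inside the analysis window), with the published quality bands
  (>70% high, 50–70% medium, <30% too degraded) and detection of
  high-molecular-weight cross-link peaks (~3,000–4,000 nt).
- **%CV reproducibility** — per-gene `100 · sd/mean` across replicates on
  the linear scale, compared between groups by a cube-root-transformed
  two-sample t-test with Cohen's *d*.
- **Concordant relative gene expression** — for each gene, within-group
  replicate ratios `r_A = a_j/a_b`, `r_B = b_j/b_b` (each replicate *b*
  serving as basis once) are concordant at cut-off *c* if both lie in
  `[1/c, c]`, both exceed *c*, or both fall below `1/c`; rates are
  reported at the conventional cut-offs 1.3, 1.5, 1.7 and 2.0. A
  group-mean variant compares fold-changes across platforms
  (e.g. microarray vs RNA-seq).
- **Top-N rank recovery** — how many of one dataset's N highest-expressed
  genes are recovered near the top of the other, with binned rank
  differences.
- **3′/5′ bias** — per-gene `log10(signal at most-3′ position / signal at
  most-5′ position)` from exon-level tables; positive medians indicate
  the 3′ signal excess typical of degraded input.
- **qPCR summaries** — geometric-mean Cq ± sd and abundance ranking by
  `ΔCq = Cq(reference) − Cq(gene)`.
- **DE screening filter** — per-gene t-test on log2 signals with a signed
  fold-change gate (`|FC| ≥ 2`, `p ≤ 0.05`) producing gene lists for
  external pathway analysis.

A synthetic-data generator produces every input class (paired
triplicate expression matrices with known discordant genes,
electropherograms with controlled DV200 and optional cross-link peak,
exon tables with a known 3′/5′ gradient, paired Cq tables with a known
offset), so the whole pipeline is testable against ground truth without
any repository download.

## Worked example

```r
library(ffpeqc)

sim <- simulate_expression_pair(sim_params(n_genes = 5000, seed = 42))
sim$expr
#> <expression_set> 5000 genes x 6 samples (log2 scale)
#>   groups: FF (n=3), FFPE (n=3)

tr <- simulate_electropherogram(trace_params(target_dv200 = 62,
                                             crosslink_peak = c(3500, 4),
                                             seed = 42))
assess_rna_quality(tr)
#>   dv200 category crosslink_peak peak_center_nt peak_prominence
#> 1  61.9 medium   TRUE                     3485            90.0
```

The measured DV200 of 61.9% recovers the simulated 62% target: medium
quality, i.e. usable for profiling with increased input — and the
detected peak near 3,500 nt warns of residual cross-linked nucleic acids
that longer tissue lysis would reduce.

```r
concordance_curve(sim$expr, "FF", "FFPE")
#>   cutoff  rate
#> 1    1.3  36.2
#> 2    1.5  67.1
#> 3    1.7  82.7
#> 4    2    91.7

glance(cv_percent(sim$expr, "FF"))$median_cv    # 9.13
glance(cv_percent(sim$expr, "FFPE"))$median_cv  # 17.7
cv_compare(cv_percent(sim$expr, "FFPE"), cv_percent(sim$expr, "FF"))
#>   statistic   df   p.value cohens_d ...
#> 1      37.7 9998 1.20e-290    0.754
```

Roughly 92% of genes keep their relative expression structure at the
±2-fold cut-off even though the FFPE-like group is twice as noisy on a
per-gene basis (median %CV 17.7 vs 9.1) — the single-gene view is
degraded, the whole-transcriptome view is preserved. The t-test is
overwhelmingly "significant" at these sample sizes; Cohen's *d* is what
tells you whether the difference matters.

```r
top_n_rank_comparison(group_means(sim$expr, "FF"),
                      group_means(sim$expr, "FFPE"),
                      n = 100, bin_edges = 400)$bins
#>   category        n_genes percent
#> 1 in top 100 of B      89      89
#> 2 |drank| <= 400       11      11
#> 3 |drank| > 400         0       0
```

`run_pipeline(pipeline_config(...))` chains all stages and writes a
report bundle (per-metric TSVs, `summary.json`, Newick dendrogram,
`report.txt`) that is byte-identical for identical seeds. Result objects
have `tidy()`, `glance()` and `autoplot()` methods; see the methods
vignette (`vignettes/ffpe-concordance.Rmd`) for the models, parameter
choices and limitations.

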