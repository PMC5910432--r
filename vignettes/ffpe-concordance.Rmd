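---
title: "Judging FFPE expression data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging FFPE expression data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeqc)
```

# The problem

Formalin fixation preserves tissue morphology by cross-linking
biomolecules, but the same chemistry fragments RNA, creates abasic
sites, and cross-links nucleic acids to proteins. Expression data from
formalin-fixed paraffin-embedded (FFPE) material is therefore noisier
than fresh-frozen (FF) data from the same cases, and the two form
*different data entities*: absolute signals must not be pooled or
compared directly. Two questions follow, and this package answers both:

1. **Is this RNA usable at all?** Classical integrity numbers rest on
   ribosomal peaks that FFPE extracts no longer have, so quality must be
   read from the fragment-size distribution and from functional (qPCR)
   behaviour.
2. **How much of the biological signal survives?** Since absolute
   comparisons are out, reliability is measured indirectly: per-gene
   reproducibility, correlation structure, preservation of *relative*
   expression (concordance), rank stability of the top-expressed genes,
   and positional 3′/5′ bias.

# Quality metrics from electropherograms

An electropherogram is a fluorescence-vs-fragment-size trace. `dv200()`
integrates it by the trapezoid rule inside an analysis window and
reports the percentage of area above 200 nt.

Numerical choices:

* **Boundary handling.** When 200 nt falls between grid points, the
  crossing trapezoid is split by linear interpolation, so the score is
  independent of grid placement; a grid point at exactly 200 nt splits
  trapezoids at the boundary. Agreement with an independent trapezoid
  oracle on randomized traces is required to 1e-9 relative in the tests.
* **Analysis window.** The default lower bound of 25 nt excludes the
  lower-marker peak of small-RNA chips. It is configurable; vendor
  software handles the marker internally and does not document how.
* **Mass, not molarity.** DV200 is defined here as the fluorescence-area
  fraction, the common vendor convention. Molarity weighting would
  require dye-binding assumptions the trace alone does not support.
* **Baseline.** Exported traces are normally baseline-corrected, so
  subtraction is off by default; a constant-baseline flag exists.

`classify_quality()` applies the published input scale: DV200 > 70% high
quality, 50–70% medium (use more input), < 30% too degraded. That scale
leaves 30–50% undefined; the package reports `"unassigned"` there rather
than inventing a category, because the practical recommendation in that
range genuinely differs between assays.

`detect_high_mw_peak()` flags putative residual cross-linked species: a
local maximum in the 2,500–5,000 nt region whose height exceeds twice
the median fluorescence of the rest of the trace. This plateau-median
rule was chosen over full topographic prominence because it directly
formalises the visual criterion used when inspecting traces (a
"well-delimited peak after the plateau"); it is simple, monotone in the
peak height, and has one interpretable knob (`prominence_factor`).

# Reproducibility: %CV and its comparison

`cv_percent()` computes per-gene `100·sd/mean` (sample sd, n−1) across a
group's replicates. It works on **linear-scale** signals by default —
sd/mean of log2 values is not the coefficient of variation, and for
log-normal noise with log2-sd σ the linear %CV is approximately
`100·ln(2)·σ` for small σ, which is the quantity practitioners quote. A
`scale = "log2"` option exists for sensitivity analysis. Genes with
non-positive means or non-finite values are excluded *and counted*, so
genes-in always equals genes-used plus genes-excluded.

`cv_compare()` cube-root-transforms each %CV set before an unpaired
two-tailed pooled t-test. The cube root symmetrises the right-skewed CV
distribution while remaining defined at zero (unlike the log). At
transcriptome sample sizes any difference is "significant", so Cohen's
*d* (difference of transformed means over pooled sd) is reported as the
effect size that actually matters.

# Concordant relative gene expression

The central reliability statistic. For two groups measured on the same
cases with n paired replicates each, and each replicate b serving as
basis once, the within-group ratios `r_A = a_j/a_b` and `r_B = b_j/b_b`
(j ≠ b) form pairs classified at a fold-change cut-off c:

* both in the closed band `[1/c, c]` → concordant (no relevant change),
* both above c → concordant (up-regulated in both),
* both below 1/c → concordant (down-regulated in both),
* anything else → discordant.

Choices worth making explicit:

* **Closed band.** A ratio exactly equal to c counts as "within". The
  convention is documented rather than consequential: ties at the
  boundary have measure zero in real data.
* **Strict mismatch rule.** One ratio within the band and the other
  beyond it is a mismatch. A lenient reading (count it as concordant
  because neither direction is contradicted) would raise every rate;
  the strict reading is implemented because the statistic's purpose is
  to *bound* trust in FFPE data, and `aggregation = "per_pair"` already
  provides the softer view.
* **Gene call per basis.** How the (n−1) ratio pairs of one basis
  combine into a gene-level call is a genuine open choice. The default
  requires *all* pairs to match (`all_pairs`); `per_pair` reports the
  pair-level rate instead. Both are exposed; the default is the
  conservative one.
* **Linear ratios.** Fold-changes are linear quantities; log2 input is
  converted via `2^x` before ratios are formed.
* **Not monotone in c.** A pair like (1.6, 3.0) matches at c = 1.5
  (both up) but mismatches at c = 2.0 (one within, one above). Rising
  concordance with rising cut-off is an empirical property of data, not
  an identity, and the tests treat it only as a tendency on synthetic
  data.

`group_mean_concordance()` applies the same pair rule to
case-mean/control-mean ratios computed in two datasets (e.g. FFPE
microarray vs fresh-tissue RNA-seq) over the intersected gene universe;
id mapping between platforms is the caller's responsibility.

`replicate_ratio_concordance()` is exactly invariant under multiplying
either group by a positive constant, which is why the group-offset term
in the simulator (below) does not affect it.

# Rank comparisons and the DE filter

`top_n_rank_comparison()` ranks genes by group-mean expression (rank 1 =
highest; ties broken lexicographically by gene id for determinism — real
signal ties are vanishingly rare) and follows dataset A's top N through
dataset B: the special bin "found within B's top N", then binned
absolute rank differences. `delta_cq_rank()` provides the qPCR
counterpart via `ΔCq = Cq(reference) − Cq(gene)`, excluding the
reference itself (its ΔCq is identically zero).

`de_filter()` is a *screening* filter, not an inferential procedure: a
per-gene pooled t-test on log2 signals (Welch optional), a signed linear
fold-change (`−1/ratio` encodes down-regulation), and the conventional
gates `|FC| ≥ 2`, `p ≤ 0.05`. No multiple-testing correction is applied,
matching its downstream use — producing candidate lists for pathway
over-representation services, which are robust to list contamination in
a way single-gene claims are not. Genes with zero variance in both
groups are flagged, not dropped silently.

# The synthetic-data generator

The generator defines the study conditions the package is tested under;
its defaults were chosen once, before looking at any downstream result,
and describe a paired FF/FFPE design:

| Parameter | Default | Why |
|---|---|---|
| `n_replicates` | 3 | biological triplicates per group |
| `base_log2_mean`, `base_log2_sd` | 7, 2 | typical normalized-array signal range |
| `noise_sd_a` (FF-like) | 0.15 log2 | linear median %CV ≈ 10%, the upper edge of high-quality reference-RNA arrays |
| `noise_sd_b` (FFPE-like) | 0.30 log2 | ≈ double the FF %CV, the degradation penalty seen in practice |
| `group_offset_log2` | −0.5 | global FFPE signal shift; cancels in every ratio |
| `frac_discordant`, `fc_injected` | 0.05, 4 | a small set of genes whose replicate structure (injected into even replicates) is inverted in group B, violating the concordance rule by construction |
| `ffpe_offset_cycles` | 5 | FFPE templates amplify several cycles later than FF |
| rRNA peaks | 1,900 / 4,700 nt | standard eukaryotic 18S/28S lengths |
| cross-link peak centre | ~3,500 nt | the 3,000–4,000 nt high-MW species seen in under-lysed FFPE extracts |

The FFPE trace is a two-component mixture: a gamma-shaped fragment
density split strictly at 200 nt into a below-200 and an above-200
component (the optional cross-link Gaussian is folded into the latter),
each normalised by trapezoidal area and mixed with weights `1 − d` and
`d = target_dv200/100`. Because the components have disjoint support
with respect to the 200 nt boundary split, the measured DV200 equals the
target *exactly* at zero noise, and stays within a fraction of a point
at the default 2% multiplicative noise. The tests require recovery
within ±3 points across targets 30–90%.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: probe-level hybridisation and
normalisation artefacts, gene–gene correlation (genes are independent),
intensity-dependent variance (the %CV is constant across the signal
range, whereas real arrays show higher CV at low signal),
sequence-dependent fixation damage, and batch structure. The FF trace
profile is qualitative only: peak heights and smear weight are not
calibrated to any instrument, so it supports peak-location and
shape checks but no quantitative claims.

# Determinism and numerical conventions

* All generator randomness flows from one integer seed per call
  (`withr::with_seed`), one stream per output; the pipeline derives
  sub-seeds from its master seed. Identical configurations give
  byte-identical report bundles; no timestamps are written.
* UPGMA clustering (distance `1 − r` on log2 signals) sorts samples
  lexicographically before linkage so distance ties resolve identically
  regardless of input column order.
* The signal scale is always *declared* (constructor argument, sample
  sheet metadata line), never inferred from value ranges.
* Degenerate inputs fail loudly with classed conditions
  (`ffpeqc_invalid_input`, `ffpeqc_undefined_metric`): zero-area traces,
  constant samples in correlations, singleton groups, missing reference
  genes. The pipeline downgrades exactly one of these to a flagged NA —
  the CV comparison on noise-free data, where a zero pooled variance is
  the expected outcome of a legitimate configuration.

# Problem sizes

The test-suite defaults are chosen to exercise every code path at
desk scale: oracle comparisons on 2–6 samples and ≤ 5 genes (where
exhaustive enumeration is feasible), parameter-recovery sweeps with
400–1,000 genes over 10 seeds, Monte-Carlo checks at 5,000 genes, and
pipeline runs at 200–300 genes. The acceptance script runs the default
study conditions at 20,000 genes. All sizes are package choices and are
trivially increased by the corresponding parameters.

# Known limitations

* DV200 is only as good as the trace: saturated detectors, unsubtracted
  baselines, or marker bleed-through bias it, and the package assumes
  these were handled upstream.
* The concordance statistic requires paired replicates
  (`replicate_index`); for unpaired designs only the group-mean variant
  is appropriate.
* Cross-platform comparisons intersect on caller-supplied shared gene
  ids; no annotation mapping is attempted.
* Normalisation (RMA or otherwise), RIN computation, read alignment and
  pathway enrichment are out of scope: the package consumes normalized
  matrices and produces gene lists.
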