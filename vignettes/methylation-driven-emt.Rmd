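---
title: "Methods: methylation-driven EMT scoring and cfDNA deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-driven EMT scoring and cfDNA deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylEMT)
```

# Scope and model

Tumor cells can escape therapy by undergoing an epithelial-to-mesenchymal
transition (EMT): epithelial genes (e.g. *CDH1*, *EPCAM*) are silenced
while mesenchymal effectors (*VIM*, *CDH2*, *ZEB1/2*, ...) are induced.
When this program is driven by DNA methylation, it leaves a readable
footprint: epithelial gene promoters gain methylation, mesenchymal gene
promoters lose it. methylEMT implements the computational machinery to
detect and monitor that footprint, in cell-line models (methylation
arrays, TAB-assay 5hmC data, RNA-seq/RT-qPCR) and in patients (targeted
bisulfite sequencing of cell-free DNA).

The analyses are organized around a 50-gene EMT signature (16 epithelial,
34 mesenchymal genes). The packaged copy
(`inst/extdata/emt_signature_synthetic.tsv`) is a *synthetic stand-in*:
it contains the canonical markers and the 13 genes excluded from cfDNA
analysis, with class labels constrained to reproduce the documented class
totals (16/34 before exclusion, 9/28 after); it is not a published
supplementary table, and analyses accept any user signature via
`read_signature()`.

# Expression scoring

`cpm_log2fc()` normalizes counts to counts per million and reports
`log2((CPM_res + 1) / (CPM_par + 1))`; the pseudocount of 1 CPM handles
zeros symmetrically, which makes the statistic antisymmetric under sample
exchange. `ddct_log2fc()` implements delta-delta-Ct with data-driven
housekeeper selection: among the five candidates (*ACTB*, *B2M*,
*GAPDH*, *UBC*, *YWHAZ*), the two with the lowest Ct standard deviation
pooled across all samples and conditions are used. Stability is measured
on raw (duplicate-averaged) Ct; amplification-efficiency normalization is
assumed upstream.

`emt_expression_score()` contrasts the two signature classes with a
Mann-Whitney U test. The test is implemented in-package
(`mann_whitney()`): exact enumeration of all rank assignments when both
classes have at most 8 members (or `n + m <= 10`), and a tie-corrected
normal approximation without continuity correction otherwise. The
"full EMT" call requires mesenchymal median log2FC > 0, epithelial
median < 0, and p < 0.05. Sidedness defaults to two-sided (main-figure
convention) and is exposed for the one-sided variants.

# Differential methylation and the overlap test

`classify_dmcs()` calls a CpG hypermethylated when
`beta_parental < 0.3` and `beta_resistant > 0.7`, hypomethylated in the
mirrored case — strict inequalities, so boundary values are stable.
Promoters are the strand-aware window 2000 bp upstream to 500 bp
downstream of the TSS (inclusive, 1-based); strand-awareness is our
choice ("upstream" is biologically strand-relative; the convention is
documented rather than inferred). CpGs in overlapping promoters count
for every gene, since per-gene means are computed independently.

`overlap_binomial()` asks whether two resistance models share more
differential CpGs than chance. On the `N` CpGs assayed in both models
(missingness filtered pairwise), with `n_A`, `n_B` differential and `k`
shared, the expected overlap is `n_A * n_B / N` and
`p = P(X >= k)`, `X ~ Binomial(n_small, n_large / N)`. Conditioning on
the smaller count makes the test symmetric; the alternative
conditionings and a hypergeometric null are exposed as options. The tail
is summed in log space; tests verify it against `pbinom` to 1e-12 and
against a permutation null (which is exactly hypergeometric — the
binomial approximation tracks it only while the sampling fractions
`n/N` are small, which is the regime of use).

# 5hmC bins and TET activity

With constant TET-mediated turnover, 5hmC tracks 5mC; a change in local
TET activity decouples them. `compare_variable_vs_stable()` bins CpGs by
5mC decile per sample (half-open bins, top bin closed) and compares the
5hmC of hyper-/hypomethylating CpGs to stable CpGs within each analysis
bin (1-3 and 8-10; the middle bins contain no variable CpGs by
construction of the 0.3/0.7 thresholds). "Stable" means any CpG not
called hyper or hypo. `tet_activity_signature()` condenses the pattern
into a flag: one-sided per-bin rank tests (variable above stable in low
bins, below in high bins, each in the sample where the variable group
resides), Stouffer-combined per side; the flag fires when both sides are
significant at 0.05. A sign-based conjunction would fire in roughly a
quarter of null datasets; requiring directional significance brings the
null rate near zero while retaining full power at the simulated effect
sizes.

# Panel design and the cfDNA mixture model

`select_target_cpgs()` keeps CpGs whose mean beta across a healthy-blood
cohort is strictly below 0.03 (pairwise-complete means);
`build_capture_regions()` merges targets within 200 bp and pads regions
to at least 60 bp — a reproducible stand-in for vendor probe tiling,
whose published statistics (28,025 probes, median 149 bp) are treated as
descriptive.

Measured cfDNA methylation is modeled as
`M_meas = M_tumor * f_ctDNA + M_cfDNA * (1 - f_ctDNA)`. On panel CpGs
`M_cfDNA ~ 0`, so `estimate_f_ctdna()` fits the through-origin
least-squares slope of `M_meas` on the tumor-reference methylation
(cohort mean of the tumor reference), clamps it to `[0, 1]`, and
bootstraps CpGs for a 95% interval. The through-origin form follows
directly from the mixture equation; a free-intercept fit is available as
a diagnostic. CpGs below 10 reads are masked (our choice; depth
filtering is otherwise unspecified), and estimates below `f = 0.01` or
with fewer than 50 CpGs are flagged unreliable —
`reconstruct_tumor_methylation()` (`M_hat = min(1, M_meas / f)`)
refuses them rather than dividing by a noisy near-zero value.

Thirteen EMT markers are excluded from patient scoring
(`exclude_unreliable_markers()`): genes whose promoter methylation in
healthy-control cfDNA exceeds 0.05 in mean or across-control standard
deviation (caps are ours; the defaults reproduce the designated 13 on
synthetic controls), or that lack panel CpGs entirely (distinct reason
code). `emt_trajectory()` then tracks, per timepoint, the reconstructed
epithelial minus mesenchymal promoter methylation relative to the first
reliable timepoint; a shift beyond `tau = 0.05` (absolute methylation;
our classifier — the underlying study reports trajectories
descriptively) is called `emt_shift`, below `-tau` `reverse_shift`.
Tissue-liquid concordance (`correlate_tissue_liquid()`) is the Spearman
correlation between tissue betas and reconstructed `M_hat` — the
"corrected for ctDNA fraction" reading we implement; a partial
correlation against raw `M_meas` would be an alternative reading, and
neither is claimed to be the original procedure.

# The synthetic world

All generators derive platform-stable streams from one seed
(Mersenne-Twister, fanned out by `derive_seed()`), so equal seeds give
byte-identical fixtures. Defaults encode the emulated study: cohorts of
656 blood and 370 tumor reference samples, 12 patients (6 acquired
resistance with samples at onset / on treatment / progression, 3 durable
responders, 3 intrinsically resistant), 16 healthy controls' worth of
structure, ~100x coverage. CpG counts are scaled to desk size (10,000
CpGs, 5,000 panel targets versus 485k/47,569 on the array) — tests
scale further down and say so.

Stated-world choices, fixed once:

* **Blood betas.** Designated target CpGs draw per-sample betas around
  per-CpG means forming a 96%/4% clean/contaminated mixture (means
  ~0.005 and 0.125, overall 0.01). The contaminated tail is what makes
  strict panel selection meaningful; after selection the retained blood
  background is ~0.005, which keeps the deconvolution bias within
  0.01. Non-target CpGs are bimodal (0.2/0.8).
* **Tumor betas.** Target-CpG reference means are bimodal — 45% near
  0.8, 55% near 0.073, overall mean 0.4 — reflecting the all-or-nothing
  character of CpG methylation; the spread also conditions the slope
  estimate well.
* **Unreliable markers.** Every subject's cfDNA carries +0.10
  methylation at the promoters of the 13 designated markers, invisible
  to the blood-array reference (different substrate). This reproduces
  the phenomenon that forces marker exclusion and contributes a small,
  bounded upward bias to `f` estimates.
* **EMT state mapping.** A patient's EMT state in `[0, 1]` linearly
  interpolates signature-promoter methylation between extremes 0.1 and
  0.8 (epithelial promoters rise, mesenchymal promoters fall with the
  state). No quantitative state-to-methylation mapping exists for real
  patients; this interpolation is a flagged stand-in.
* **5hmC turnover.** `h = kappa * m * (1 - m)`: monotone coupling of
  5hmC to 5mC at fixed turnover `kappa`, vanishing at m = 0 and 1. Any
  monotone coupling would serve; this one is simple, configurable
  (`tet_kappa` switched 0.4 to 0.1 for hypermethylating CpGs, reversed
  for hypomethylating, 0.25 for stable), and analytic for oracle tests.
* **Counts.** Depth is Poisson (negative-binomial expression counts use
  dispersion 0.3); sequencing error and fragmentomics are out of scope.

What a green test establishes: parameter recovery, calibration, and
exact inversions *within this stated world*. The generators do not
emulate array normalization artifacts, probe biases, cell-composition
variation in blood, or copy-number effects on cfDNA — claims about real
data require the real accessions.

# Numerical and degenerate-input policy

Betas outside `[0, 1]` are validation errors on input, clipped-and-
counted in the generator (error above 10% clipped). Missing values are
excluded pairwise everywhere. Zero-depth coverage records are retained
but flagged; division by an unreliable `f` is refused, not silently
propagated. The binomial tail and the rank tests guard the `p = 1` and
zero-variance edges explicitly. Internal coordinates are 1-based
inclusive (Bismark convention); BED export converts to 0-based
half-open.

# A worked desk-scale run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_cpgs = 2000, n_target_cpgs = 800,
                  n_blood = 30, n_tumor = 25)
run_pipeline(cfg, "run1")
read.delim("run1/deconv.tsv", comment.char = "#")[1:3, ]
```

Every stage is also exposed as a CLI subcommand (`emt_cli()`, wrapper in
`inst/cli/emtmeth`): `simulate`, `design-panel`, `diffmeth`, `overlap`,
`score-emt-expression`, `score-emt-methylation`, `tet-bins`, `deconv`,
`trajectory`, `tissue-corr`, `run-all`.

# Known limitations

* The packaged signature is synthetic; per-gene class labels of the 13
  excluded markers are constrained by class totals only.
* The binomial overlap null ignores finite-population effects; use the
  hypergeometric option when `n/N` is not small.
* `f` estimates inherit a small positive bias from residual cfDNA
  background methylation; it is bounded by design of the panel (clean
  retained background) but not corrected.
* Trajectory classification depends on `tau` and on reliable `f` at two
  or more timepoints; sparse or shallow series degrade to `no_shift`
  rather than guessing.
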