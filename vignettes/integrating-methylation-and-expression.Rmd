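---
title: "Integrating DNA methylation, gene expression and TF binding across cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating DNA methylation, gene expression and TF binding across cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methintegrate)
```

## Overview

`methintegrate` implements a multi-omic integration workflow for panels of
cell types profiled by RRBS (per-CpG methylated/unmethylated read counts),
450K-style arrays (per-probe beta values), RNA-seq differential expression
(log2 fold changes) and TF ChIP-seq peak sets. The workflow has four
statistical cores:

1. **Cell-type-specific differential methylation.** Per shared CpG passing a
   read-depth filter (default ≥ 10 reads in both samples), a two-sided
   Fisher exact test on the methylated/unmethylated 2×2 table, BH-corrected;
   DMCs require an absolute methylation difference ≥ 25 percentage points at
   q ≤ 0.01. DMCs aggregate into tiling-window DMRs (mean difference ≥ 20
   points, q ≤ 0.01; a *significant* tier additionally requires q ≤ 0.001
   and ≥ 5 DMCs). A cell type's specific DMRs are obtained by set deduction:
   a DMR survives only if it overlaps no DMR of any other cell type in the
   panel.
2. **Genomic partitioning.** Six regions built from CpG islands, their
   1,000 bp shores and 2,000 bp TSS-centered promoters: islands and shores
   outside promoters (I, II), islands and shores inside promoters (III, IV),
   promoter bases outside islands (V) and outside islands-and-shores (VI).
3. **A Bayesian Gaussian regression** of differential expression on
   methylation, tumor-suppressor status and genomic segment, sampled by
   Gibbs, with Chib log marginal likelihoods and Bayes-factor model
   selection.
4. **A Beta-background Kolmogorov–Smirnov classifier** of TF–methylation
   interplay at promoters.

A synthetic-data module generates multi-cell-type methylomes, expression
tables and TF peak grids with full ground truth, so every stage is
exercisable and testable without any download.

## The regression model

For annotated gene $i$ hosting a DMR,

$$\mathrm{DGE}_i = \mathrm{Methy}_i\,\beta_1 + \mathrm{TSG}_i\,\beta_2 +
\beta_3(\mathrm{GS}_i) + \varepsilon_i,\qquad \varepsilon_i \sim N(0,\sigma^2),$$

where $\mathrm{DGE}_i$ is the log2 fold change, $\mathrm{Methy}_i$ the
signed mean methylation difference of the hosting DMR in percentage points
(positive = hyper-methylated), $\mathrm{TSG}_i$ a binary tumor-suppressor
indicator, and $\mathrm{GS}_i$ the hosting segment (gene body, intron,
promoter, 5'UTR, 3'UTR or CDS). Segments are cell-means coded — one
indicator per segment, no global intercept — so each segment's coefficient
is directly interpretable; $\beta_1$ and $\beta_2$ are shared across
segments. Although the model could in principle carry gene-specific
coefficients, one coefficient per predictor (and per segment) is the
reading under which per-segment summaries are meaningful, and it is the one
implemented.

Priors are semi-conjugate and proper:
$\beta \sim N(b_0, B_0^{-1})$, $\sigma^{-2} \sim \Gamma(c_0/2, d_0/2)$,
with weak defaults $b_0 = 0$, $B_0 = 10^{-4} I$, $c_0 = d_0 = 0.002$. A
proper prior is a hard requirement: the marginal likelihood is undefined
under improper flat priors. The Gibbs sampler alternates the two full
conditionals (a multivariate normal for $\beta$ given $\sigma^2$, a gamma
for $\sigma^{-2}$ given $\beta$). The reference schedule is 500,000
iterations with the first 1,000 discarded; the package default of 10,000 +
1,000 is ample for the simulation studies shipped here, because the
two-block sampler mixes essentially instantly on full-column-rank designs
(effective sample sizes close to the draw count).

**Segment insufficiency.** Segments with fewer than `min_n = 50` rows are
dropped from the design and recorded, mirroring the automatic omission of
sparse segments (3'UTR in typical panels, with tens of genes against
hundreds for the other segments). The exact cutoff is a judgment call; 50
cleanly separates the sparse-3'UTR regime from the rest while leaving the
fit comfortably identified.

**Marginal likelihood.** The Chib single-point identity
$\log m(y) = \log p(y\mid\theta^*) + \log p(\theta^*) -
\log p(\theta^*\mid y)$ is evaluated at the posterior mean $\theta^* =
(\beta^*, \sigma^{2*})$. The $\beta$ ordinate is Rao–Blackwellised over the
retained $\sigma^2$ draws; with only two Gibbs blocks, the $\sigma^2$
ordinate given $\beta^*$ is its exact full conditional, so no reduced run
is needed. The estimator refuses to run on fewer than 1,000 retained draws
(the ordinate average is too noisy below that). On a four-observation toy
problem it agrees with direct 2-D quadrature of the evidence integral to
well under 0.05 nats (see the test suite and `scripts/acceptance.R`).

**Model selection.** Posterior model probabilities under equal prior odds
are computed from log marginal likelihoods through log-sum-exp, which is
exact at magnitudes around $10^3$ where naive exponentiation underflows.
The canonical comparison is the base model against a variant adding HPRO, a
binary hyper/hypo indicator derived from the sign of Methy. Because Methy
already carries that sign, HPRO duplicates information and the Bayes factor
penalizes the extra parameter; simulations without any HPRO effect select
the base model in well over 90% of replicates.

## What the synthetic generator emulates — and what it does not

`simulate_methylomes()` draws one shared CpG site catalogue (RRBS enriches
a common set of MspI fragments across samples), negative-binomial coverage
floored at a configurable minimum (so both passing and failing sites exist
for the depth filter), and binomial methylated counts around per-site
proportions from a per-cell beta mixture — one to three components,
emulating the unimodal/bimodal/trimodal landscapes seen across real cell
types. Proportions are clamped to [0.01, 0.99] before the binomial draw so
downstream Beta fits never see exact 0/1. Per-cell missingness is added by
independent dropout (default 10%).

Cross-cell dependence uses a Gaussian copula: each site carries a latent
normal shared across cells with weight `site_rho` (default 0.8), mapped
through each cell's mixture quantile function. Marginals remain exactly the
specified mixtures, while pairwise methylome correlations land near 0.7 at
the default — the range real RRBS panels show. `site_rho = 1` makes
per-site proportions identical across cells with the same spec, which is
the strict per-site null used for false-positive calibration; planted DMRs
(`planted_dmr()`) shift the target cell's proportions by a fixed effect
size inside an interval, giving ground truth for recovery studies.

Not modelled: read-level data (no FASTQ), bisulfite conversion error,
strand-specific coverage, sequence context, spatial autocorrelation of
methylation beyond the planted intervals, and array-specific probe biases.
Passing recovery tests therefore demonstrates the *callers'* correctness
under binomial sampling noise, not robustness to alignment or conversion
artifacts in real data.

`simulate_expression()` generates gene tables directly from the regression
model with recorded residuals, so the linear-predictor identity holds
exactly; Methy values are signed uniforms over 20–80 points (the range
DMR-hosted genes actually show after the ≥ 20-point DMR threshold).
`simulate_tf_peaks()` gives each (cell, TF) combination either background
promoter methylation (Beta(2,2) by default), a shifted beta
(default Beta(1,4), emulating TFs preferring lowly-methylated promoters),
or no peaks at all — the gray "null" class. Defaults (15% of combinations
shifted, 100 CpGs per combination) were chosen so the aggregate background
stays representative; because a tested combination's own values stay inside
the aggregated background (no leave-one-out), heavy contamination by
strongly shifted combinations makes the classifier flag pure-background
combinations too — a known conservatism of the aggregate-background design,
visible in the demo if you raise `fraction_shifted`.

## Numerical and design choices

- **Fisher exact test.** Implemented vectorized over sites via the
  fixed-margin hypergeometric distribution with the standard
  relative-likelihood two-sided rule (tolerance $1+10^{-7}$), memoised over
  unique tables. It matches `stats::fisher.test` and brute-force
  enumeration to $10^{-12}$ on all tables with total count ≤ 40; the
  vectorized form is what makes 50-replicate genome simulations affordable.
- **Multiple testing.** BH step-up throughout (`stats::p.adjust`), applied
  separately per family: tested CpGs, tested windows, tested TF
  combinations.
- **DMR construction.** Fixed 1,000 bp tiling (width = step by default);
  windows qualify on pooled counts, and adjacent qualifying windows with
  the same direction merge. The merged interval's mean difference is
  recomputed from pooled counts; its q-value is the minimum member-window
  q — deterministic and conservative for the tiering rule, since merging
  never manufactures significance. The DMC count of a DMR counts
  *qualifying DMCs* inside it, not covered CpGs.
- **Set deduction.** Any-base overlap, direction-agnostic, half-open
  coordinates (abutting intervals do not block). Deduction is idempotent,
  and subsetting to the significant tier first is the default for
  specificity analyses.
- **Promoters and shores.** Promoter = TSS ± 1,000 bp clipped at chromosome
  bounds. Shore = 1,000 bp on each side of a merged island, minus island
  bases — so shores of adjacent islands never double-count. The phrase
  "1,000 bp centered around the island" could also mean a 500 in/500 out
  band; the width is exposed as `shore_flank` rather than fixed.
- **Region VI.** Promoter bases outside islands *and* shores (the shore
  band conceptually wraps the island), which is the reading under which
  regions V and VI nest the way the worked examples require.
- **KDE modality.** Gaussian KDE, Silverman bandwidth by default, evaluated
  on a grid spanning [−0.05, 1.05] and truncated to [0, 1] to suppress
  boundary-artifact modes; modes are local maxima with topographic
  prominence ≥ 5% of the global peak. That prominence floor suppresses
  micro-modes while reproducing the uni/bi/tri classes on beta mixtures.
- **K-S against the background.** One-sample, against the fitted Beta CDF,
  asymptotic p-values; values clamped by $10^{-6}$ before CDF evaluation.
  The background fit is method-of-moments by default ($k = m(1-m)/v - 1$,
  $\alpha = mk$, $\beta = (1-m)k$), with an MLE refinement available.
  Combinations with fewer than `min_sites = 50` measured CpGs are classed
  "null" rather than tested.
- **Degenerate inputs.** Constant KDE input, empty K-S vectors,
  over-dispersed Beta samples ($v \ge m(1-m)$), rank-deficient designs,
  sub-1,000-draw Chib requests and missing reference cells all raise named
  errors rather than propagating NaNs.

## Study sizes used in the shipped simulations

The test suite and acceptance script run deliberately compact studies:
regression recovery at $n = 1000$ genes with 10,000-iteration chains
(50 replicates in the suite), model recovery at $n \approx 400$ with
4,000-iteration chains, DMR recovery on 100 kb single-chromosome genomes
with ~1,200 CpGs (50 replicates), null calibration on 500-window genomes
(20 replicates), and K-S power at 300 CpGs per combination. These sizes
were chosen as the smallest at which the studied properties are stable
across seeds; the same functions run unchanged at reference scale
(`mcmc_iterations = 5e5`, genome-wide site counts).

## Known limitations

- The per-site Fisher test assumes independent reads; RRBS fragment-level
  dependence is not modelled (the same assumption the standard toolkits
  make without replicates).
- The Eq.-style regression treats one (gene, hosting DMR) pair per row;
  genes hosting several DMRs contribute the largest-overlap DMR only.
- The aggregate K-S background includes each tested combination's own
  values; with few, strongly shifted combinations this is conservative for
  the shifted ones and anti-conservative for background ones (see above).
- Array/RRBS concordance is computed on raw proportions, not
  logit-transformed values; with exact-position joins only.

## A three-minute demo

```{r demo, eval = FALSE}
cfg <- default_pipeline_config(out_dir = tempfile("demo_"), seed = 7)
state <- run_pipeline(cfg)

state$reports$concordance$mean_offdiag_r   # cross-cell methylome correlation
state$reports$dmr$n_dmrs                   # per-cell consensus DMR sets
state$reports$specific$n_specific          # surviving cell-specific DMRs
state$comparison                           # base vs +HPRO Bayes factors
table(state$interplay$class)               # TF-methylation classes
```

In the pipeline demo a cell type's DMR set is the consensus of its pairwise
comparisons — regions where it differs from *every* other cell in the same
direction — which is the construction under which the set deduction of one
cell's regions against the union of the others' is informative.
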