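# methintegrate

Integration of DNA methylation, gene expression and transcription-factor
binding across cell-type panels, for epigenomics analysts working with
RRBS methylomes, 450K-style beta tables, RNA-seq differential expression
and ChIP-seq peak sets.

The package implements, as tested reusable functions:

- **DMC/DMR discovery with set-deduction specificity.** Per-CpG two-sided
  Fisher exact tests (coverage ≥ 10 in both samples), BH correction, DMC
  thresholds |Δmeth| ≥ 25 points at q ≤ 0.01; tiling-window DMRs (mean
  difference ≥ 20 points, q ≤ 0.01; significant tier q ≤ 0.001 with ≥ 5
  DMCs). A cell type's *specific* DMR set is

  DMR̂ᵢ = DMRᵢ \ ⋃_{j≠i} DMRⱼ,

  the set deduction of its DMRs against the union over all other cell
  types (any-base overlap, half-open coordinates).
- **Six-region genomic partition** from CpG islands, 1,000 bp shores and
  2,000 bp TSS-centered promoters: islands/shores outside promoters (I,
  II), inside promoters (III, IV), promoter bases outside islands (V) and
  outside islands-and-shores (VI); plus CpG feature assignment and
  DMR–tumor-suppressor-gene segment overlap.
- **A Bayesian Gaussian regression** of differential expression:
  DGEᵢ = Methyᵢ β₁ + TSGᵢ β₂ + β₃(GSᵢ) + εᵢ, εᵢ ~ N(0, σ²), with
  semi-conjugate priors β ~ N(b₀, B₀⁻¹), σ⁻² ~ Γ(c₀/2, d₀/2), fitted by
  Gibbs sampling; Chib log marginal likelihoods and Bayes-factor model
  selection (e.g. against a variant adding the redundant binary
  hyper/hypo indicator HPRO).
- **A Beta-background K-S classifier** of TF–methylation interplay:
  promoter methylation pooled over all (cell, TF) combinations fits a Beta
  background by moments; each combination is K-S-tested against it,
  BH-corrected, and classed highly-differentiated / lowly-differentiated /
  null.
- **A synthetic-data module** (shared CpG catalogue, negative-binomial
  coverage, beta-mixture landscapes with a cross-cell Gaussian copula,
  planted DMRs, model-generated expression, TF peak grids) with full
  ground truth, so the whole pipeline runs and is tested without any
  download.

## Worked example

```r
library(methintegrate)
cfg <- default_pipeline_config(out_dir = tempfile("demo_"), seed = 7)
state <- run_pipeline(cfg)
```

The synthetic demo simulates three cell types (4,000 shared CpGs, six
DMRs planted in the reference cell), and runs every stage. With seed 7 it
prints:

```r
state$reports$concordance$mean_offdiag_r
#> [1] 0.7037483            # cross-cell methylome correlation
state$reports$dmr$n_dmrs
#> cellA cellB cellC
#>     9     7     9        # per-cell consensus DMR sets
state$reports$specific$n_specific
#> [1] 2                    # reference DMRs surviving set deduction
state$comparison
#>       model log_marginal_likelihood selection_probability
#> 1      base                -424.157            0.99795654
#> 2 with_hpro                -430.348            0.00204346
table(state$interplay$class)
#> highly-differentiated  lowly-differentiated            null
#>                     5                     7               6
```

The comparison table reads: the base regression model is preferred over
the base + HPRO variant with posterior probability ≈ 0.998 under equal
prior odds, because the sign of Methy already carries the hyper/hypo
information HPRO duplicates. The interplay table splits the 3 × 6
(cell, TF) grid into combinations whose promoter methylation deviates
from the pooled Beta background (adjusted p ≤ 0.05), those that do not,
and those with too few measured CpGs to test.

Posterior summaries of the regression fit (true generator values:
β_Methy = −0.02, β_TSG = 0.5, σ = 0.5):

```r
summarize_posterior(state$fit)$summary
#>   coefficient    median      lo      hi
#> 1       Methy -0.020091 -0.0209 -0.0193
#> 2         TSG  0.584597  0.4944  0.6796
#> ...
#> 8      sigma2  0.234858  0.2081  0.2665
```

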