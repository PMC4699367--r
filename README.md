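# tukinetics

Quantifying pre-mRNA splicing and RNA decay kinetics from ultra-short
metabolic RNA labeling (4tU/4sU) time courses.

## The problem

Pulse-labeling cellular RNA with 4-thiouracil for very short times (1.5,
2.5 and 5 minutes) and sequencing the purified nascent RNA captures
transcripts *before* splicing and degradation have run to completion. Two
kinds of kinetic questions become answerable transcriptome-wide:

* **How fast is each intron spliced?** For an intron-containing gene, the
  splicing ratio `R = mRNA / (mRNA + pre-mRNA)` rises over labeling time
  toward its steady-state value; the shape of that rise ranks genes by
  splicing speed.
* **How fast do unstable non-coding RNAs decay?** For CUTs, SUTs and XUTs,
  nascent abundance relative to steady state is a decay-rate proxy, and
  their early kinetics depart visibly from first order (multi-step, delayed
  degradation).

This package implements the full analysis as a tidyverse-style R library,
for computational biologists working with such time courses — and ships a
synthetic 4tU-seq simulator with explicit kinetic ground truth so every
stage is testable without sequencing data.

## The statistics at its core

**Probabilistic splicing ratio.** Each aligned fragment carries a latent
identity (precursor or mature). Junction fragments are unambiguously
mature, intron-touching fragments unambiguously precursor, exon-only
fragments ambiguous. With ψ the read-level mature fraction and effective
lengths ℓ̃ (isoform length − mean fragment length + 1), a Gibbs sampler
alternates

1. each ambiguous fragment's identity from
   `P(mature) = ψ/ℓ̃_m / (ψ/ℓ̃_m + (1−ψ)/ℓ̃_p)`, and
2. `ψ ~ Beta(a + n_mature, b + n_precursor)` (exact conjugate update),

yielding the posterior mean and a 95% credible interval of the molar ratio
`R = (ψ/ℓ̃_m) / (ψ/ℓ̃_m + (1−ψ)/ℓ̃_p)`. Genes whose interval is wider
than 0.3 at any nascent time point are filtered out. Two direct estimators
(junction/boundary counts; intron/exon coverage densities) are provided for
comparison, and an estimator benchmark reproduces the probabilistic
model's lower variance at low coverage.

**Splicing speed.** Per gene, the trajectory collapses to

    AUC = [ (R_2.5 + R_1.5)/2 + 2.5 (R_5.0 + R_2.5)/2 ] / (3.5 R_SS)

the trapezoidal area under the ratio curve normalized by the steady state:
AUC = 1 means splicing is already at steady state by 1.5 min; larger is
faster.

**Decay proxy.** `log2(weighted mean nascent FPKM / steady-state FPKM)` —
higher means faster decay.

**Background bound.** With α₀ and α₁ the intronic FPKM fractions of the
mock (0-min) and 1.5-min samples and β ≤ 0.5 the signal's intronic
fraction, mass balance bounds the unlabeled contamination:
`m/n = (β − α₁)/(α₁ − α₀)`, background fraction ≤ `(m/n)/(1 + m/n)`.

Around these sit intron feature extraction (folding energy per nucleotide
via a built-in dynamic-programming proxy or ViennaRNA, splice-site PWM bit
scores, k-mer composition) and the associated statistics (thirds-based
Wilcoxon comparisons, feature–speed Pearson correlations with BH
adjustment, 10-fold cross-validated Gaussian naive Bayes ROC/AUC,
random-forest regression with out-of-bag evaluation).

## Worked example

```r
library(tukinetics)

# a single-intron gene with known kinetics, simulated and re-estimated
params <- kinetic_params(k_syn = 10, k_splice = 2, k_decay = 1)
truth  <- simulate_labeled_abundances(params, times = c(1.5, 2.5, 5))
model  <- test_gene_model()
reads  <- simulate_reads(truth, model, n_fragments = 2000, seed = 3)
est    <- posterior_ratio(reads, model, seed = 1)
dplyr::select(est, time, n_reads, ratio, ratio_lo, ratio_hi)
#> # A tibble: 4 × 5
#>    time n_reads ratio ratio_lo ratio_hi
#>   <dbl>   <int> <dbl>    <dbl>    <dbl>
#> 1   1.5    2000 0.504    0.469    0.540
#> 2   2.5    2000 0.616    0.581    0.647
#> 3   5      2000 0.646    0.616    0.678
#> 4   Inf    2000 0.687    0.656    0.718

truth$ratio      # the simulated truth the estimates recover
#> [1] 0.4803128 0.6036760 0.6617110 0.6666667

splicing_speed(est)$auc   # near 1: most splicing already done by 1.5 min
#> [1] 0.8886077

# the published desk arithmetic, recomputed
worked_examples()
#> # A tibble: 3 × 4
#>   quantity                 value units ...
#> 1 yield_fit_r_squared      0.959 R^2
#> 2 fold_enrichment_1.5min   2.32  fold
#> 3 background_bound_percent 9.18  %
```

The first block shows the estimator tracking the true ratios within its
credible intervals at 2000 fragments; the AUC near 1 says this gene's
splicing is nearly at steady state already at 1.5 min. `worked_examples()`
reproduces three published values: the linearity of RNA yield with
labeling time (R² ≈ 0.96), the ≥2-fold enrichment of labeled over
background yield at 1.5 min, and the ≈9.1% upper bound on mRNA background
contamination.

A full synthetic run — simulate, count, quantify, filter, speeds, decay,
features, statistics, with per-stage TSVs and a checksum manifest — is one
call:

```r
res <- run_pipeline(default_run_config(), "my_run")
```

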