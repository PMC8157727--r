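---
title: "Detecting differential RNA reactivity from probing counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential RNA reactivity from probing counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffprobe)
```

## The problem

Chemical structure probing (SHAPE, DMS and their mutational-profiling
variants) reads out RNA flexibility per nucleotide: a reagent modifies
flexible/single-stranded positions, and modification sites appear in
sequencing data either as reverse-transcription stops or as mutations.
Comparing two probing conditions — wild type vs mutant, in-cell vs
deproteinized — asks which nucleotides changed reactivity: the
*differentially reactive nucleotides* (DRNs). The statistical difficulty is
that raw per-position signals mix chemistry with coverage-dependent counting
noise and substantial replicate-to-replicate variability, and thousands of
positions are interrogated at once.

diffprobe works entirely from raw counts (coverage and event counts per
position per sample) and produces a posterior probability of differential
modification per nucleotide, avoiding both reactivity normalization
heuristics and per-position hypothesis testing with its multiplicity burden.

## The statistical pipeline

For each condition separately:

1. **Event rates.** `r_i = d_i / c_i` per sample, missing (never zero)
   where coverage is below `max(1, coverage_threshold)`.
2. **Log rate-ratios (LDR/LMR).** Natural-log ratios `log(r_t / r_c)` for
   *every* treatment-control pair (2 treatments x 2 controls give 4
   comparisons per position) and for every ordered pair of distinct
   controls (k controls give k(k-1) *null* comparisons). A zero rate on
   either side makes the cell missing: a position must register events in
   both samples to contribute a finite, informative ratio. Ordered control
   pairs make the pooled null exactly sign-symmetric, since
   `log(a/b) = -log(b/a)`.
3. **Variance stabilization.** Counting noise makes log-ratios wider at low
   coverage. Null log-ratios are binned by paired coverage into quantile
   bins and the family `sd(n) = sqrt(k1 + k2/n)` — a constant replicate-
   variability floor plus binomial sampling noise decaying as `1/n` — is
   least-squares fitted to per-bin mean squares (the null is centred at 0
   by symmetry), with non-negativity enforced by projection. All
   log-ratios are divided by the predicted `sd(n)`.
4. **Empirical P-values.** Each stabilized treatment-control value is
   compared to the pooled, sorted null with the upper-tail add-one
   estimator `p = (1 + #{null >= obs}) / (N + 1)`. P-values of unmodified
   positions are (slightly super-) uniform by construction; modified
   positions concentrate near 0. No distributional assumption enters.

The two conditions' P-value tracks are then decoded **jointly** by a
four-state hidden Markov model over per-position states UU, UM, MU, MM
(U = unmodified, M = modified; first letter condition 1). Emissions are a
beta-uniform mixture: each non-missing P-value contributes a uniform factor
(density 1) under its condition's U component and a `Beta(alpha, beta)`
factor under M. Transitions encode that modified stretches are short
(expected run length `l_ss`) and unmodified stretches long (`l_ds`), via
self-transition `1 - 1/L` per the geometric run-length identity; the joint
4x4 matrix is the Kronecker product of the per-condition 2x2 chain with
itself, i.e. the conditions are a priori independent and only the data
couple them. The forward-backward algorithm yields exact posterior
marginals; the quantity of interest is `P_diff = P(UM) + P(MU)`.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `l_ss` | 5 nt | expected modified (single-stranded) run length; short loops/bulges |
| `l_ds` | 20 nt | expected unmodified (double-stranded) run length; helices are long |
| `alpha`, `beta` | 1, 10 | Beta shape of P-values under modification; the density crosses the uniform at `1 - 0.1^(1/9) ~ 0.226`, so P-values below ~0.2 favour modification |
| `coverage_threshold` | 0 | per-sample coverage floor for a position to be decodable |
| `call_threshold` | 0.95 | `P_diff` level for a DRN call |
| `initial_dist` | stationary | start distribution of the chain; the stationary law is the unique translation-consistent choice deep inside long segments (uniform available) |
| `n_bins` | 10 | coverage quantile bins for the variance fit |
| `null_min_size` | 100 | minimum pooled null size for usable P-value resolution |

`alpha` is restricted to (0, 1] and `beta` to [1, Inf) so the Beta density
is non-increasing in p — small P-values must never count *against*
modification. The defaults can be refined per dataset with
`fit_beta_em()`, an EM whose E-step takes modified-component weights from
forward-backward decoding and whose M-step maximizes the weighted Beta
log-likelihood by projected Newton ascent with backtracking (the
observed-data log-likelihood is non-decreasing by construction). The
default parameters are used for reported analyses; EM is off unless
requested (`em = TRUE`).

## Numerical choices

- **Scaled vs log-space recursions.** The production forward-backward uses
  scaled recursions (stable for segments of 100,000+ positions); a
  log-space implementation is kept as an independent route and the two
  agree to 1e-10 in the test suite. Per-position log-emission maxima are
  subtracted before exponentiation; since the UU emission is always
  density 1, every scaling constant is strictly positive.
- **p = 1 inputs.** Legal (the add-one estimator never produces p = 0 but
  p = 1 occurs); with `beta > 1` the M-component log-density is `-Inf`,
  which the recursions propagate as exact zero posterior mass for
  M-containing states — never NaN. In the EM M-step such observations
  carry exactly zero weight and are dropped.
- **Paired coverage.** Each comparison cell's coverage predictor is the
  *harmonic* mean of the two samples' coverages: the sampling variance of
  a log rate-ratio is additive in reciprocal coverages
  (`1/n_a + 1/n_b = 2/n_harm`), so the fitted family is exact under
  binomial noise even for strongly imbalanced pairs, where an arithmetic
  mean understates the variance.
- **Variance fit against `E[1/n]`.** Bins are regressed on the per-bin mean
  of `1/n`, not `1/mean(n)`, because `E[LDR^2 | bin] = k1 + k2 E[1/n | bin]`
  holds exactly for the model family.
- **Ties and degeneracies.** Null ties count toward the upper tail;
  `call_drns()` breaks argmax ties toward the lowest state index (UU
  first) and direction ties toward condition 1 — deterministic and
  documented. Positions missing all P-values in either condition are
  excluded at segmentation and break the chain, so each contiguous
  decodable stretch is decoded independently.

## Design decisions that were genuinely open

- **Denatured normalization** (mutational-profiling data) is implemented as
  division of treated and control rates by the floored per-position mean
  denatured rate (floor 1e-3, cap 10). Division of rates, rather than
  rescaling of counts, keeps the operation local and the downstream
  log-ratios finite; the exact formula is not standardized in the field,
  so floor and cap are exposed as configuration.
- **Null construction** uses ordered control pairs and pools across all
  transcripts of a run, maximizing null size (per-transcript pooling would
  be a trivial variant); the add-one estimator is a `O(1/N)` perturbation
  that keeps log-emissions finite.
- **Transition matrix by Kronecker product.** A joint 4x4 chain could in
  principle be learned by EM; the independence construction from the
  per-condition run-length chain is used instead, with both conditions
  sharing (`l_ss`, `l_ds`). The matrix is overridable in code, and the
  test suite includes a robustness check: halving or doubling the
  off-diagonal rates changes the strong-signal DRN call set by under 5%.

## The synthetic-data generator

`simulate_dataset()` emulates the generative assumptions at desk scale so
the whole pipeline is testable end to end with known ground truth:
condition-1 states from the two-state run-length chain; condition-2 states
copied, then each maximal condition-1 run flipped with probability
`differential_fraction` — flipping whole runs (rather than positions)
produces the contiguous UM/MU stretches that real structural changes and
the transition prior both imply. Coverage is negative binomial (mean 5000,
dispersion 5, a desk-scale echo of the high-coverage regime these methods
target); events are binomial at baseline rate 0.002, elevated 10-fold at
modified sites of treated samples; replicate variability is log-normal
jitter (sd 0.1) per sample and position. `modified_multiplier = 1` yields
the identically-treated null regime in which treatments are exchangeable
with controls. Default problem sizes used throughout the tests and the
acceptance script are 10 transcripts x 1000 nt for pipeline-level checks,
20,000 positions for EM recovery and 50,000 draws for variance-model
recovery.

What the generator does **not** model: sequence-content biases,
position-level artifacts shared across samples or conditions, saturation
of heavily modified sites, ligation/priming biases, or read-level
structure (it works at count level by design). Passing tests therefore
demonstrate correctness of the statistics under the stated generative
assumptions, not performance on any particular real dataset.

## Known limitations

- **Correlated comparisons bound null specificity.** With 2 treatments and
  2 controls, the four P-values per condition at a position share samples
  and are pairwise correlated (~0.5): both counting noise and replicate
  jitter are per-sample quantities entering every comparison that uses the
  sample. The product-form emission treats the P-values as independent, so
  on data with *no* modification signal anywhere and fully independent
  conditions, a few percent of positions acquire appreciable `P_diff` —
  the acceptance script quantifies this on the identically-treated
  simulation. On real data this is mitigated because position-level
  artifacts tend to push both conditions alike (absorbed into MM/UU) and
  genuinely modified sites dominate the small-P-value mass; users should
  nevertheless treat isolated single-nucleotide calls with conservative
  thresholds and replicate support. More replicates per condition dilute
  the correlation.
- Posterior mass bleeds a few nucleotides beyond the true edges of strong
  differential runs — inherent to run-length smoothing and visible in the
  recovery simulations.
- The posterior quantifies evidence of *change*, not magnitude: inspect
  the underlying rates alongside calls to judge effect sizes.
- Paired-end-derived counts are assumed upstream; the package neither
  aligns reads nor collapses duplicates.
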