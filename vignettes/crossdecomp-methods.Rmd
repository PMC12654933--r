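---
title: "Cross-validated spectral decomposition: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated spectral decomposition: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crossdecomp)
```

## The problem

Two neural systems — repeated trials of one subject, two subjects, or two
brain regions — respond to the same `n` stimuli with matrices `X` (`n × d_X`)
and `Y` (`n × d_Y`). We want the *spectrum* of stimulus-related variance they
share: how much reliable, generalizing covariance lives along each latent
dimension, as a function of the dimension's rank. A spectral view is what
lets one ask whether representations are confined to a few dominant
dimensions or decay smoothly without a characteristic scale (a power law),
and whether two individuals use the same latent dimensions at all ranks.

Plain PCA cannot answer this: its eigenvalues mix stimulus-driven signal
with trial noise, and two subjects' covariances live in different channel
spaces. The estimator implemented here addresses both with one construction.

## The cross-decomposition estimator

Per cross-validation fold:

1. **Alignment (training).** Center the training rows of each side by their
   own column means and take the SVD of the cross-covariance
   `C = (1/n) t(Xc) %*% Yc = U S t(V)`. `U` and `V` are orthonormal
   rotations into a shared latent space — the Procrustes / PLS-SVD
   transform used by hyperalignment. The training singular values `S` are
   nonnegative and absorb all covariance, reliable or not.
2. **Evaluation (held-out stimuli).** Center held-out rows by the
   *training* means, rotate (`X U`, `Y V`), and take the diagonal of the
   latent-space covariance. These test values are *signed*: a dimension
   whose training alignment does not generalize has expected value zero.

`fit_cross_basis()` and `evaluate_test_spectrum()` implement the two steps;
`within_system_spectrum()`, `between_system_spectrum()` and
`anatomical_spectrum()` wrap them over an 8-fold stimulus split
(`make_folds()`), channel-normalize, and return per-fold tidy spectra.

Conventions that matter, and why:

- **Covariance scaling is `1/n`** (population) on both train and test, and
  channel z-scoring (`zscore_channels()`) likewise uses the population
  standard deviation. Jointly these make the normalization identity exact:
  after full-set z-scoring, the channel covariance has trace `d`, so the
  training spectrum of a self-decomposition, divided by the geometric mean
  `sqrt(d_X d_Y)` (`normalize_by_channels()`), sums to exactly 1.
- **Test rows are centered with training means** when projecting — the test
  set must not inform the transform. The latent-space covariance then
  subtracts the *projections' own sample means* (the standard covariance).
  This second subtraction is load-bearing: without it, the fold-mean offset
  `mean(X_test U) * mean(Y_test V)` — which contains shared signal and
  survives any row permutation — becomes the conditional mean of the
  permutation null, displacing it from zero by tens of Monte-Carlo standard
  errors at desk scale. With it, a row shuffle has *exactly* zero expected
  spectrum conditional on the data, and the in-sample identity
  (test = train reproduces the training singular values) still holds
  exactly because training projections are exactly mean-zero.
- **Retained rank** is `K = min(d_X, d_Y, n_train − 1)`; centering removes
  one degree of freedom. Fold spectra are truncated to the smallest K
  across folds so ranks align.
- **Signs.** Training singular values are kept nonnegative; within each
  pair `(u_k, v_k)` the largest-magnitude element of `u_k` is made
  positive. Spectra are invariant to these choices. Ordering among exactly
  tied singular values is implementation-defined; tests avoid exact ties.
- **Symmetrized between-system estimate.** Trial order is arbitrary, so
  the between-subject (or between-region) spectrum averages the two
  cross-trial pairings, `(S(X1, Y2) + S(X2, Y1)) / 2`.

### Comparison estimators

`pca_spectrum()` returns the raw eigenvalues (signal plus noise).
`cvpca_spectrum()` learns axes from trial 1 over the *full* stimulus set
and evaluates the covariance of both trials' projections — reliability
across repeats without generalization to new stimuli, which is exactly what
distinguishes it from the cross-decomposition; consequently it takes no
fold plan. On shared-signal-plus-noise data the three estimators order as
expected: PCA above cvPCA at low rank, cvPCA above cross-decomposition in
the noise-dominated tail.

## Binning, fold aggregation, power-law fits

Raw per-rank test values are noisy at high rank; averaging within bins of
exponentially increasing width trades rank resolution for sensitivity,
extending the detectable range by orders of magnitude. `make_log_bins()`
builds geometrically spaced edges; the default 2.75 bins/decade over ranks
1–10⁴ yields 11 bins. Membership is `edge_j <= k < edge_{j+1}` (last bin
right-inclusive); edges are snapped to the integer endpoints so boundary
ranks always fall inside.

Order of aggregation: each fold's spectrum is binned, then bins are
averaged across folds (`bin_spectrum()` then `aggregate_folds()`). The
alternative order gives the same means but different dispersions; the
reported `sd` is the *population* standard deviation across folds (a
factor `sqrt(8/7)` below the sample convention at 8 folds), consistent
with the covariance convention.

`fit_power_law()` is unweighted OLS of `log10(mean)` on
`log10(bin_center)` over strictly positive bins in a stated rank interval.
Negative bin means are retained in the data (the estimator is signed) but
excluded from fitting and drawn as open symbols. For recovery analyses the
default fit interval is ranks 1–100: two decades, clear of the rank limit
where boundary bias sets in (below).

## Permutation null and significance

`build_null_ensemble()` repeats the identical pipeline with the second
side's held-out rows shuffled within each test fold — fresh independent
permutations per fold and draw — and returns the per-bin 68/95/99th
percentile envelopes (5,000 draws by default). Because of the covariance
convention above, the ensemble mean is zero up to Monte-Carlo error.
`flag_significance()` computes one-sided add-one p-values,
`p = (1 + #{null ≥ observed}) / (n_perms + 1)`, never exactly zero, with
default `alpha = 0.001`; the test is one-sided because genuine shared
signal is positive by construction, and the null is symmetric, so this is
conservative for negative bins. No multiple-testing correction is applied
across bins — flags are per-bin descriptions, matching standard practice
for spectral envelopes.

## Spectral correlation

`spectral_correlation()` forms, per (wide) bin,
`r = between / sqrt(within_X * within_Y)` from fold-averaged binned
spectra — a correlation-like ratio in which every term is cross-validated,
so chance alignment cannot inflate it. Ratios amplify noise, so wider bins
(default 2/decade) are used than for the spectra themselves. A bin is
valid only where both within-means are strictly positive; bins whose
between-mean is under three across-fold standard deviations are flagged
(open symbols). The across-fold dispersion of per-fold ratios is reported
where the per-fold denominators are positive.

## The synthetic testbed

`generate_ensemble()` draws the structure the estimators assume:

- latent signals with variances `lambda_k ∝ k^(-alpha)` normalized to sum
  to `n_latent`, Gaussian by default (no heavier-tailed option is exposed;
  the estimators only see second moments);
- per subject, a mixture of a common latent draw
  (weight `sqrt(shared_fraction)`) and a private draw with the same
  variance profile, so `shared_fraction` *is* the expected spectral
  correlation at every rank;
- random orthonormal channel embeddings per subject, with an optional
  leading block of `n_aligned_latents` columns shared across subjects
  (anatomically aligned dimensions);
- independent white trial noise (`noise_sd`), then per-channel population
  z-scoring, emulating standard preprocessing. `zscore = FALSE` yields
  exact rotated copies for algebraic checks.

Defaults mirror a two-subject, two-trial natural-scenes comparison: 766
stimuli, exponent 1.6, fully shared latents, and `noise_sd = 1` against
per-channel signal variance of order one (single-trial fMRI-like
reliability). 512 channels keeps every analysis tractable on a laptop
while leaving two-plus decades of rank structure. `expected_spectra()`
returns the closed-form targets (within: `lambda_k`; between:
`shared_fraction * lambda_k`) used by the recovery tests.

What the generator does *not* emulate: spatial autocorrelation of fMRI
noise, session drift, hemodynamic structure, heavy-tailed responses, or
stimulus-set diversity effects. Passing tests therefore establish that the
estimators recover known second-order structure under clean conditions —
not that real cortical spectra are power laws.

### Finite-size behavior worth knowing

Two boundary effects of SVD-based alignment show up reliably in synthetic
data and shape how the package's own validation is set up:

- **Rank-limit bias.** Learned directions near the retained rank `K` mix
  quasi-degenerate latents, flattening the spectrum's tail: binned means a
  few percent high where the true values are tiny, far outside the tiny
  across-fold dispersion. Reliability near the rank limit is poor in real
  data for the same reason. Closed-form comparisons in the test suite
  therefore assert agreement away from the rank limit (bins whose ranks
  stay below `K/2`).
- **Alignment-boundary mixing.** With `m` anatomically aligned leading
  latents, the singular pairs just beyond rank `m` are quasi-degenerate
  with the strong aligned pair at rank `m` and mix with it under finite
  sampling, leaking aligned variance a few ranks past the boundary. The
  anatomical-vs-functional comparison therefore uses bins wide enough
  (2/decade) that this mixing zone stays inside the bin containing rank
  `m`; with 1,024 stimuli, 256 channels and the default noise level the
  anatomical spectrum then loses significance precisely beyond the rank-10
  bin while the functional spectrum stays significant at least two bins
  further — the synthetic analogue of anatomical alignment detecting only
  the first ~10 shared dimensions.

## Gabor encoding baseline

`build_gabor_bank()` enumerates quadrature pairs of Gabor filters
(`gabor_kernel()`: Gaussian envelope × sinusoidal carrier) over 3 envelope
scales (σ = 0.025, 0.050, 0.075 in relative image units), 3 carrier
frequencies per scale, 8 orientations uniform on `[0, π)`, and an 8 × 8
grid of centers in `[−0.45, 0.45]` — 4,608 pairs, 13,824 features (odd,
even, energy = odd² + even²). The frequency rule is exposed as a
convention flag because the customary printed form multiplies a frequency
by a length: `"multiply"` (`f = c·σ`, taken literally, the default) gives
sub-cycle filters; `"divide"` (`f = c/σ`) puts a fixed number of carrier
cycles under the envelope. Both are implemented; tests that need band-pass
behavior use `"divide"`. Kernels are sampled on a full 128×128 raster by
default, without truncation or norm normalization — per-feature z-scoring
absorbs scale.

`ridge_loocv()` fits voxel-wise encoding weights with the shrinkage chosen
per target from a grid (default 30 values, 10⁴–10⁸, matching feature
matrices of ~10⁴ z-scored columns) by *closed-form* leave-one-out error via
the hat-matrix identity — one SVD, no refit loop — and equals the explicit
n-refit LOO to numerical precision. No intercept is fit; inputs are
expected centered/z-scored. `model_vs_neural_spectrum()` then runs the
cross-decomposition between measured responses and model predictions and
reports the normalized cumulative shared-variance curve, on which a
low-rank model saturates visibly earlier than the data.

## Representational similarity controls

`compute_rsm()` (Pearson pattern correlations), `rsa_correlation()`
(Pearson or Spearman over the strictly upper triangle — the diagonal is
uninformative and would inflate agreement), `low_rank_reconstruct()` (PCA
truncation with the mean restored), and `bootstrap_rsa()` (90% stimulus
subsampling without replacement, 5,000 resamples, 2-sd error bars)
implement the variance-weighting control: reducing one subject to its 10
leading components moves the RSA correlation by ≤ 0.05 while the
cross-decomposition spectrum of the same reduced data loses every
significant bin beyond rank ~10. Single-trial patterns are used
throughout. Euclidean-distance RDMs and whitened/crossnobis variants are
out of scope.

## Orchestration and reproducibility

`run_spectrum()`, `run_correlation()` and `run_rsa()` take a plain named
list (or YAML file) and write figure-ready CSVs plus a JSON log of every
parameter. All randomness flows from two named seeds (`seed_folds`,
`seed_perms`); every output embeds the config hash and seeds, and reruns
with identical configs are byte-identical. Timings are logged to the
console only, never to files.

## Problem sizes used in validation

The package's own test suite validates at sizes chosen to finish within a
coffee break while leaving clear margins: oracle equivalence on 200 random
small instances (≤ 20 × 8); the normalization identity on 500 × 200;
permutation-null centering with 5,000 draws on 240 × 120; exponent
recovery (±0.15 for α ∈ {1, 1.6, 2}) at 4,096 stimuli × 512 channels; the
alignment ceiling at 1,024 × 256 with 1,000 permutations; and the RSA
control at 512 × 128. The fitted-exponent interval (ranks 1–100) and the
boundary-bin exclusions are stated above and fixed once.

## Known limitations

- The estimator is linear; a nonlinear manifold could be lower-dimensional
  than its linear spectrum suggests.
- Power-law fits describe the binned spectrum's slope; the package makes
  no attempt to discriminate power laws from lognormal or cutoff
  alternatives, which would require far larger spectral ranges.
- Ridge/shrinkage-regularized alignment and CCA are not implemented; the
  alignment is plain Procrustes/PLS-SVD as described.
- Near the rank limit and at alignment boundaries the estimator has the
  finite-size biases described above; conclusions about those ranks should
  lean on the permutation null, not the raw means.
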