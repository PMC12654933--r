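# crossdecomp

Cross-validated spectral decomposition of the stimulus-related variance
shared between high-dimensional neural response sets.

## What problem this solves, and for whom

Given responses of two neural systems to the same stimuli — repeated
trials of one subject, two subjects, or two brain regions, as `n stimuli ×
d channels` matrices of fMRI betas, spike counts, or similar — this
package estimates the *spectrum* of reliable shared variance as a function
of latent-dimension rank. That spectral view is what lets you ask whether
a population code is confined to a handful of dominant dimensions or is
scale-free (a power law with no intrinsic dimensionality), and whether two
individuals share their latent dimensions at all ranks or only the leading
few. It is aimed at systems/cognitive neuroscientists analysing large
stimulus-set recordings, and at methodologists who need a
noise-robust, generalization-tested alternative to PCA, cvPCA, or RSA.

## The estimator

Per stimulus fold (8 by default):

1. **Align** on training stimuli: center each side by its training means
   and decompose the cross-covariance

   `cov(X, Y) = (1/n) Xcᵀ Yc = U Σ_train Vᵀ`,

   the Procrustes / PLS-SVD transform used by hyperalignment; `U`, `V`
   rotate each system into a shared latent space.
2. **Evaluate** on held-out stimuli: `Σ̂_k(X, Y) = diag cov(X_test U, Y_test V)`,
   with test rows centered by the *training* means. These test values are
   signed, and a dimension whose alignment does not generalize has
   expected value 0 — so a permutation null is exactly centered, and
   significance per bin comes from 5,000 row-shuffled re-evaluations.

Spectra are divided by `sqrt(d_X d_Y)` (so a z-scored self-decomposition
sums to 1), averaged within exponentially widening rank bins and across
folds, and summarized by a log-log power-law slope. The between-subject
spectral correlation at rank bin `k` is

`r_k(X, Y) = Σ_k(X, Y) / [Σ_k(X1, X2)^½ Σ_k(Y1, Y2)^½]`,

a correlation coefficient in which numerator and denominator are all
cross-validated. Baselines included for comparison: PCA, cvPCA, an
anatomical-alignment variant (projections swapped at test time), a Gabor
energy encoding model with closed-form ridge LOOCV, and RSA with the
low-rank control. A synthetic generator with known power-law latent
structure makes every estimator testable end to end without any data
download.

## Worked example

```r
library(crossdecomp)

# two synthetic subjects, two trials each: 512 stimuli, 128 channels,
# power-law latents (alpha = 1.6), single-trial noise
ens <- generate_ensemble(synth_config(n_subjects = 2, n_stimuli = 512,
                                      n_channels = 128, alpha = 1.6,
                                      noise_sd = 1, seed = 42))
x <- ens$responses[[1]]; y <- ens$responses[[2]]

folds  <- make_folds(x[[1]]$stimulus_ids, n_folds = 8, seed = 1)
scheme <- make_log_bins(1, 128, per_decade = 2.75)

spec <- within_system_spectrum(x[[1]], x[[2]], folds) |>
  bin_spectrum(scheme) |>
  aggregate_folds()
nul  <- build_null_ensemble(x[[1]], x[[2]], folds, scheme,
                            n_perms = 1000, seed = 2)
flag_significance(spec, nul, alpha = 0.01)
#> # A tibble: 6 × 8
#>     bin bin_center     mean        sd n_ranks n_folds  p_value significant
#>   <int>      <dbl>    <dbl>     <dbl>   <int>   <int>    <dbl> <lgl>
#> 1     1       1.41 0.120    0.0137          2       8 0.000999 TRUE
#> 2     2       3.91 0.0247   0.00266         3       8 0.000999 TRUE
#> 3     3       8.32 0.00742  0.000872        6       8 0.000999 TRUE
#> 4     4      18.0  0.00126  0.000159       14       8 0.000999 TRUE
#> 5     5      40.4  0.000218 0.0000523      32       8 0.000999 TRUE
#> 6     6      90.7  0.000112 0.0000429      71       8 0.000999 TRUE

fit_power_law(spec, fit_range = c(1, 100))
#> <power_law_fit> exponent -1.776 (amplitude 0.246, 6 bins in [1, 100])
```

Reading this: every bin of the within-subject spectrum clears the 1,000-
permutation null at p < 0.01 — reliable stimulus-related variance is
detected across the full two decades of ranks, falling on a log-log line
with slope ≈ −1.8 (the generator's −1.6 steepened slightly by noise
attenuation at high ranks). The between-subject correlation confirms the
latents are shared:

```r
wide <- make_log_bins(1, 128, per_decade = 2)
spectral_correlation(
  between_system_spectrum(x[[1]], x[[2]], y[[1]], y[[2]], folds) |> bin_spectrum(wide),
  within_system_spectrum(x[[1]], x[[2]], folds) |> bin_spectrum(wide),
  within_system_spectrum(y[[1]], y[[2]], folds) |> bin_spectrum(wide))
#> # A tibble: 4 × 6
#>     bin bin_center     r      sd valid flagged
#>   <int>      <dbl> <dbl>   <dbl> <lgl> <lgl>
#> 1     1       1.82 0.998 0.00368 TRUE  FALSE
#> 2     2       7.13 1.00  0.0185  TRUE  FALSE
#> 3     3      23.7  0.973 0.102   TRUE  FALSE
#> 4     4      79.2  0.702 0.711   TRUE  TRUE
```

`r ≈ 1` wherever the estimate is reliable (the last bin is flagged by the
three-sd rule — an open symbol in plots). `autoplot()` renders binned
spectra, null envelopes, and correlation tables; `run_spectrum()`,
`run_correlation()` and `run_rsa()` drive the same analyses from a config
list or YAML file and write figure-ready CSVs with seeds and a config hash
embedded.

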