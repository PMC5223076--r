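# trimodr

Nonlinear trimodal regression of CT radiodensitometric (HU) distributions
of skeletal muscle.

## The problem

Muscle degeneration — sarcopenic, cachectic, or following denervation — is
usually quantified on CT by the *average* Hounsfield-unit (HU) value of a
segmented muscle volume. Averaging discards most of the information in the
radiodensitometric distribution: two very different degeneration states can
share a mean HU. `trimodr` instead fits the *entire* 128-bin HU histogram
over the soft-tissue window [−200, 200] HU with a three-component
quasi-probability-density model, one component per tissue type:

- **fat** ([−200, −10] HU), a skewed Gaussian,
- **loose connective tissue / atrophic muscle** ([−9, 40] HU), a standard
  Gaussian (skewness fixed at zero),
- **normal muscle** ([41, 200] HU), a skewed Gaussian.

The model evaluated at HU value *x* is

```
f(x) = Σᵢ  Nᵢ / (σᵢ √(2π)) · exp(−(x−μᵢ)² / 2σᵢ²) · erfc(αᵢ (x−μᵢ) / (σᵢ √2)),   i ∈ {fat, connective, muscle}
```

where *N* is the amplitude (the component's total count — the erfc form
integrates exactly to *N*), *μ* the location (HU), *σ* the width (HU) and
*α* the skewness. With the connective *α* structurally zero the model has
**11 free parameters**, estimated by bounded nonlinear least squares
against the bin counts; goodness of fit is reported as *R²*. Note the sign
convention: positive *α* skews mass toward *lower* HU (the erfc form is
the mirror of the textbook skew-normal `2φΦ(λz)`, with `λ = −α`).

Around the core fit the package provides the full workflow: CT-bin to HU
conversion (`HU = CT × 3.125 − 200`), histogram construction and
tissue-interval classification, mean-HU and tissue-fraction metrics,
pre/post cohort comparison with two-tailed heteroscedastic (Welch)
t-tests, partial-volume-effect (PVE) correction that relocates the
two-pixel fat/muscle boundary layer to the tissue mean HUs, and synthetic
voxel/phantom generators with ground truth for validation. Input formats:
flat CSV of HU values, pre-binned histogram CSV, or NIfTI image + mask.

## Worked example

```r
library(trimodr)
tp  <- default_healthy_params()          # healthy-like demo parameters
hu  <- sample_trimodal(tp, 2e5, seed = 1)   # 200k synthetic voxels
h   <- build_histogram(hu)
fit <- fit_trimodal(h)
print(h)
print(fit)
cat(sprintf("mean HU: %.2f\n", mean_hu(h)))
```

```
HU histogram: 128 bins over [-200, 200] HU (width 3.125), 200000 counts
trimodal fit: R^2 = 0.999905, SSE = 131013, 28 iterations
trimodal model parameters (11 free):
  fat        component: N = 190836, mu = -79.62 HU, sigma = 21.85 HU, alpha = -1.152
  connective component: N = 54690.7, mu = 3.973 HU, sigma = 29.17 HU, alpha = 0
  muscle     component: N = 379587, mu = 55.02 HU, sigma = 13.06 HU, alpha = 1.778
mean HU: 7.99
```

The fit recovers the generating truth (fat μ = −80, connective μ = 5,
muscle μ = 55 HU; muscle σ = 13, α = 1.8) to a fraction of a bin, with
R² ≈ 0.9999. Fitted `N` values are on the count × bin-width scale:
`N / 3.125` is the component's voxel count (e.g. muscle
379587 / 3.125 ≈ 121 000 of the 200 000 voxels). The single mean-HU
number (7.99) illustrates how much the conventional metric hides: it says
nothing about the three peaks the fit resolves.

A command-line wrapper covering the same workflow (`fit`, `classify`,
`simulate`, `pve`, `compare`) is installed at `inst/cli/trimodr`:

```sh
Rscript inst/cli/trimodr simulate --n 100000 --seed 7 --out /tmp/demo
Rscript inst/cli/trimodr fit --input /tmp/demo_histogram.csv --format histogram --out /tmp/fit.json
```

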