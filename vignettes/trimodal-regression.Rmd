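---
title: "Trimodal regression of muscle HU distributions: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimodal regression of muscle HU distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimodr)
```

## The model

A segmented muscle volume on CT yields a distribution of voxel
attenuation values in Hounsfield units. Within the soft-tissue window
[−200, 200] HU this distribution is treated as *trimodal*: three tissue
types occupy largely distinct HU domains — fat ([−200, −10]), loose
connective tissue and atrophic muscle ([−9, 40]), and normal muscle
([41, 200]). The histogram is modeled as a sum of two skewed and one
standard Gaussian quasi-probability-density function,

$$ f(x) = \sum_{i=1}^{3} \frac{N_i}{\sigma_i\sqrt{2\pi}}
   e^{-(x-\mu_i)^2/2\sigma_i^2}
   \operatorname{erfc}\!\left(\frac{\alpha_i (x-\mu_i)}{\sigma_i\sqrt{2}}\right), $$

with the connective $\alpha$ fixed at zero, leaving 11 free parameters.
"Quasi" because the curve is count-scaled, not normalized: since
$\operatorname{erfc}(\alpha z/\sqrt2) = 2\Phi(-\alpha z)$ and the
skew-normal density $2\varphi(z)\Phi(-\alpha z)$ integrates to one, each
component integrates exactly to $N_i$, so $N_i$ is the component's total
count (`component_area()` verifies this identity numerically). The
skewness describes the inward-sloping asymmetry of the fat and muscle
peaks — fat tissue infiltrating upward in HU, degenerating muscle
sliding downward — while the central connective band is kept symmetric.

**Sign convention.** The erfc form above is implemented exactly as
written. It is the mirror of the textbook skew-normal
$2\varphi(z)\Phi(\lambda z)$: the two coincide with $\lambda = -\alpha$,
so *positive* $\alpha$ here pushes mass toward *lower* HU. The sampler
(`sample_trimodal()`) uses the exact two-Gaussian
$\delta$-parameterization with shape $-\alpha$, with no rejection step.

## Discretization and classification

Voxel HU values are binned into 128 uniform bins via the linear CT
transform $HU = CT \times 3.125 - 200$, with CT indices 0..128 read as
bin *edges* (edge 0 at −200, edge 128 at 200 HU). The transform is
one element ambiguous in principle (0..127 centers vs 0..128 edges); the
edge reading makes both printed endpoints exact and is used throughout.
Bins are half-open $[e_i, e_{i+1})$ with the last closed at 200. Values
outside the window are *discarded*, not clipped — the window is a
soft-tissue window by construction — and their count is reported.

The tissue intervals are printed as integer bounds (fat up to −10,
connective from −9 to 40, muscle from 41). For continuous values the
package splits at the midpoints −9.5 and 40.5 HU, an unbiased reading of
the integer gaps. Density is compared to counts directly at bin centers
(no bin-width factor), so a fitted $N$ carries an implicit bin-width
scale: a component holding $n$ voxels fits $N \approx 3.125\,n$. Raw
counts are fitted, not normalized frequencies; the histogram is the
regression target as measured.

## Fitting

The objective is ordinary least squares over the 128 bins,
$\mathrm{SSE}(\theta) = \sum_b (c_b - f(x_b;\theta))^2$, whose
minimization is equivalent to maximizing $R^2 = 1 - \mathrm{SSE} /
\mathrm{SST}$. Optimization uses bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) over the 11 free parameters with box bounds:
$N \ge 0$, $\sigma \in [0.1, 200]$ HU, $|\alpha| \le 20$ (numerical
stability of `exp`/`erfc`), and each $\mu$ anchored to its tissue
interval (fat [−200, −9.5], connective [−9.5, 40.5], muscle
[40.5, 200]). The interval anchoring is an identifiability device: it
prevents components from swapping roles mid-optimization and encodes the
trimodal tissue hypothesis. Convergence is declared at a relative SSE
change below 1e−10, with at most 1024 iterations per start (the
Levenberg–Marquardt backend's ceiling; the tolerance triggers far
earlier in practice).

**Initialization and multi-start.** `initialize_params()` starts each
component at its interval's maximum-count bin center, with
$\sigma_0 = $ interval width / 6, $N_0 = $ interval count × 3.125 and
$\alpha_0 = 0$. This is reliable for the dominant fat and muscle peaks
but fragile for the connective band: whenever the muscle peak's lower
flank exceeds the connective peak inside the connective interval — the
typical situation, since the connective band is low and broad — the
argmax start parks the connective component at the interval edge, a
local minimum that small perturbations do not escape. `fit_trimodal()`
therefore runs several starts and keeps the smallest SSE: the supplied
initialization itself, two deterministic variants that replace the
connective start with a low- and a mid-interval location and a broad
width (interval/4), and jittered copies of the initialization with fixed
sub-seeds derived from the `seed` argument. The whole procedure is
deterministic given (histogram, init, options, seed), and the final SSE
never exceeds that of the supplied initialization.

**Identifiability of the skewness.** The skew-normal family has a
singular Fisher information at $\alpha = 0$: near symmetry, $\alpha$ is
confounded with joint shifts of $\mu$ and $\sigma$. Consequently, when
the underlying component is symmetric the *curve* is recovered
essentially exactly while the fitted $\alpha$ can wander by several
tenths even at $10^6$ voxels — replicate experiments here show
truth-initialized global optima with $|\hat\alpha|$ up to ≈0.5 whose SSE
is *below* that of the generating truth. Fitted skewness near zero
should therefore be read qualitatively ("approximately symmetric"), not
as a precise estimate; the package's tests assert curve stability
(fitted curve within 2% of the true curve in sup-norm) rather than tight
$\alpha$ recovery in the symmetric case.

## Synthetic study conditions

The demonstration parameter set (`default_healthy_params()`) places
the muscle peak at 55 HU — the healthy-subject reference value — and
fixes the remaining values as documented fixture choices for a plausible
healthy adult leg: fat $(N = 5{\times}10^5, \mu = -80, \sigma = 22,
\alpha = -1.2)$, connective $(N = 1.5{\times}10^5, \mu = 5, \sigma = 30,
\alpha = 0)$, muscle $(N = 10^6, \mu = 55, \sigma = 13, \alpha = 1.8)$:
a dominant, moderately narrow muscle peak skewed toward lower HU, a
blunter fat peak skewed toward higher HU, and a low broad connective
band. The amplitude ratios (roughly 60% muscle, 30% fat, 9% connective
voxels) reflect a healthy limb with predominantly superficial fat.

Problem sizes in the validation suite were chosen so that each check is
informative: single-fit parameter recovery uses $10^6$ voxels
(location errors well under 1 HU, widths under 5%, amplitudes under 2%,
$R^2 > 0.999$); the 20-replicate location-consistency experiment uses
$3{\times}10^5$ voxels per replicate, because the broad, low-amplitude
connective band's statistical information floor for $\mu$ only drops
below 1 HU around that size — truth-initialized fits at $10^5$ voxels
already show a median connective location error near 1.8 HU, so no
optimizer can do better there.

What the generator does *not* emulate: scanner physics (beam hardening,
reconstruction kernels, noise correlation between neighboring voxels),
anatomical geometry, bone or vessel contamination of the mask, and
inter-subject parameter variability. Passing these tests shows the
estimator is correct and well calibrated under the model's own
assumptions; on real scans the trimodal model is an approximation whose
adequacy shows up in $R^2$ and the residuals.

## Cohort comparison

`compare_cohort()` compares pre- versus post-surgery parameter values,
per leg and per parameter, with two-tailed *unequal-variance* (Welch)
t-tests and flags $p < 0.05$. Two deliberate fidelity choices: tests are
unpaired even though pre and post come from the same subjects (the
heteroscedastic two-sample test is the stated protocol), and no
multiple-testing correction is applied by default — the number of
comparisons is printed so users can judge, and a Bonferroni switch is
available but off. Null calibration (flag rate ≈ 5%) and power at a
+5 SD shift (≈ 100%) are verified by simulation in the test suite.

## Partial-volume correction

Pixels on a fat/muscle interface average the two tissues' attenuation
and populate the central connective band of the histogram.
`boundary_mask()` marks fat- or muscle-labeled pixels within Chebyshev
distance 2 (8-connectivity dilation; the "two-pixel-wide" layer) of the
other tissue; connective and background pixels are never part of the
layer. `pve_correct()` then moves each boundary pixel's count from its
own HU bin to the bin containing the fat or muscle mean HU — whichever
mean is *closer in HU value* (ties to fat, deterministically). Proximity
is deliberately HU-valued, not spatial: the operation relocates counts
to tissue mean HU values, which is an HU-space notion; a spatial variant
is a possible extension. Tissue means are computed over non-boundary
pixels only. Total count is conserved exactly, and correction is the
identity when the boundary is empty.

One subtlety matters for experiments: if labels are derived from the
*observed* (blended) image via `label_image()`, the intermediate-HU
interface pixels are labeled connective and are therefore excluded from
the removable layer, and the central band cannot shrink. The phantom
experiment consequently feeds `pve_correct()` the generator's
*geometry-truth* labels, under which blended pixels keep their true
fat/muscle identity; this reproduces the near-disappearance of the
connective-band peak. On real data the analogous choice is a
morphologically cleaned (or eroded-core) label map rather than raw
voxelwise thresholds.

## Degenerate inputs and numerical notes

- `erfc` is evaluated as $2\Phi(-z\sqrt2)$ via `pnorm` — exact to machine
  precision over the bounded parameter ranges.
- An all-zero tissue interval makes initialization impossible; the error
  names the empty tissue. A constant observed histogram makes $R^2$
  undefined; `NA` is returned with a warning rather than a misleading 1.
- Non-convergence within the iteration budget flags
  `converged = FALSE` on the result instead of raising.
- Out-of-window boundary pixels (possible under heavy noise) were never
  part of the histogram and are reported but not moved, preserving exact
  count conservation.

## Known limitations

- Parameter uncertainty (confidence intervals) is not quantified; the
  method reports point estimates and $R^2$.
- The skewness estimate is weakly identified near symmetry (see above).
- The trimodal hypothesis itself is an approximation: severely
  degenerated muscle may need more flexible shapes, which are out of
  scope here.
- DICOM series ingestion is not built in; convert to NIfTI (applying
  rescale slope/intercept) upstream.
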