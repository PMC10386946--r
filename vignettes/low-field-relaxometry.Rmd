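---
title: "Quantitative T1/T2 relaxometry at low field: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative T1/T2 relaxometry at low field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrfit)
```

# Scope

`qmrfit` implements a complete desk-scale pipeline for quantitative
relaxometry on a portable low-field (tens of mT) MRI system: design of an
inversion-recovery (IR) T1 protocol by Monte-Carlo simulation, voxel-wise
T1/T2 map reconstruction with a standard-error exclusion rule, automated
phantom-tube quality assurance, skull stripping plus Gaussian-mixture
tissue binning of in vivo maps, and the reference-comparison statistics
(confidence-interval overlap, normalization, percent difference,
Bland-Altman limits of agreement) used to judge agreement between an
imaging protocol and a bench NMR reference. Because no raw scans are
distributed with such studies, every pipeline input can be generated
synthetically with known ground truth, and the test suite validates the
pipeline by parameter recovery on those digital phantoms.

# Signal models

All times are in **seconds** throughout, in code and in files.

The magnitude IR signal at inversion time $TI$ with repetition time $TR$ and
imperfect inversion $d \in (0, 1]$ is

$$S(TI) = S_0 \left| 1 - (1+d)\,e^{-TI/T_1} + e^{-TR/T_1} \right|,$$

with `ir_signal()` implementing it and `ir_signal_full_recovery()` its
$TR \gg T_1$ limit (used for bench NMR series acquired with $TR > 5T_1$).
The spin-echo decay is the monoexponential $S(TE) = S_0 e^{-TE/T_2}$
(`se_signal()`). The default inversion scale is $d = 0.95$; $d$ is treated
as a fixed protocol property, never a fitted parameter (a deliberate match
to the original analysis, which lists only $S_0$ and the relaxation time as
fit targets).

Magnitude images carry **Rician** noise: `add_rician_noise()` returns
$\sqrt{(S+g_1)^2 + g_2^2}$ with $g_1, g_2 \sim N(0, \sigma^2)$. SNR is
defined as $S_0/\sigma$ with $\sigma$ the per-channel SD — the conventional
choice; the source study never defines it. The simulation assumes
$\sigma$ constant across inversion times.

`ir_null_time()` returns the analytic zero crossing
$T_1 \ln\frac{1+d}{1+e^{-TR/T_1}}$, used to initialize T1 fits and for
protocol sanity checks.

# Fitting

Both models are linear in $S_0$, so the least-squares problem is solved by
profiling: for any candidate relaxation time the optimal amplitude is
$\hat S_0 = \sum y_i b_i / \sum b_i^2$ (clamped at 0) with $b_i$ the unit
model, and the fit reduces to a 1-D minimization over the relaxation time —
a coarse scan on a log grid over the bounds $[1\,\mathrm{ms}, 20\,\mathrm{s}]$
followed by Brent refinement (tolerance $10^{-10}$ on $\log \tau$). This is
the same minimizer as a 2-parameter nonlinear solver, but has no
convergence failures on the flat residual surfaces of ill-conditioned
long-T1 voxels and is fast enough for the Monte-Carlo protocol search
(under a millisecond per fit). Bounds stop runaway estimates; plain least
squares is applied to magnitude data with **no Rician noise-floor
correction**, deliberately mirroring the original analysis (its stated
limitation is preserved, not fixed).

Standard errors come from the 2-parameter Gauss-Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum, with $J$ assembled from the
analytic derivatives of the signed model. A voxel is **excluded** exactly
when the fit did not converge or its standard error exceeds the estimate
itself — the rule used to discard ill-conditioned long-T1 voxels in vivo.
The magnitude of the standard error is definition-dependent (the original
text never defines "standard error of the fit"); consequently the package
asserts the *direction* of exclusion-rate changes with SNR, not absolute
rates.

`reconstruct_map()` fits every voxel independently (one value per voxel;
partial-volume unmixing is out of scope), and `fit_roi_joint()` pools all
(time, signal) pairs of an ROI into a single fit with shared $S_0$ and
relaxation time, the per-slice phantom-tube strategy.

# Protocol optimization

`simulate_t1_estimates()` generates repeated noisy IR signal sets at a
protocol's TIs ($\sigma = S_0/\mathrm{SNR}$) and refits each;
`mean_percent_error()` scores a protocol as the grid average of
$|\overline{\hat T_1} - T_1| / T_1 \times 100$ over 25 repeats — the bias
of the mean estimate, which is the ranking key. The mean per-repeat
absolute error is available via `metric = "per_repeat"` for sensitivity.

Two defaults deserve comment:

* **T1 grid.** Only the range 0.1-4 s is prescribed by the source; the
  grid density and spacing are not. The default is 40 *linearly* spaced
  points. A log-spaced grid was considered (it matches the multiplicative
  error metric) but under-weights the long-T1 regime where the short-TR
  in vivo schedule is ill-conditioned, producing roughly a third of the
  published headline error; the linear grid reproduces the published ~2%
  figure and is therefore the default, with the spacing under the caller's
  control.
* **Seed policy.** Each (T1, SNR) cell derives its own stream from the
  master seed and the cell's values (`derive_seed()`), so scores are
  comparable across candidates and invariant to grid ordering.

`rank_protocols()` drops candidates over the scan-time budget (default one
hour, at 586 s per TI series), sorts by mean error over the primary SNR
band 50-95, breaking ties by the secondary band 25-50 and then input
order. A small combinatorial generator (`generate_candidates()`) is
provided but off by default; explicit candidate lists are the expected
input. One empirical caution encoded in the tests: a 5-TI schedule with
*well-spread* TIs and a longer TR can legitimately outscore the 6-TI
optimized schedule under this metric — the documented failure mode of
sub-optimal schedules (gross misestimation at short and long T1) arises
from TI placement, specifically schedules whose TIs are compressed into a
narrow early window.

# Phantom tube analysis

`detect_tubes()` finds tube cross-sections with a gradient-voted Hough
circle transform restricted to radii within ±25% of the expected tube
radius, refines each detection to sub-voxel accuracy by taking the
centroid and equivalent-disc radius of the thresholded local patch, and
orders detections row-wise in `(y, x)` for stable IDs.
`detect_tubes_series()` propagates IDs between adjacent slices by
nearest-center matching with a 2-voxel displacement cap (the matching rule
is this package's choice; the source does not state one). Each ROI is then
shrunk to half the tube radius (`central_roi()`) to avoid wall
partial-volume, one value per tube per slice is produced (joint T1 fit, or
ROI mean of the voxel-wise T2 map), and `summarize_tubes()` reports the
mean/SD over the six central slices. With $n$ slices and $c$ central ones
the selection is slices $\lfloor (n-c)/2 \rfloor + 1, \dots,
\lfloor (n-c)/2 \rfloor + c$ (so 8 slices with values $1..8$ average slices
2-7, i.e. 4.5).

The end-to-end phantom acceptance check runs with the 29-TI reference
schedule (TR 2.8 s): with tube values spanning up to water-like
$T_1 = 4$ s, the 6-TI in vivo schedule's long-T1 ill-conditioning alone
contributes ~9% error at SNR 95, while the reference schedule recovers all
tubes within 1% — the same division of labor as in the original
validation, where the long protocol served as the imaging reference.

# Brain pipeline

`strip_skull()` thresholds (Otsu's inter-class-variance criterion by
default), opens to detach the thin skull ring and speckle, closes to fill
interior gaps, and keeps the largest connected component. The raw
inversion image may be supplied instead of the map when it gives cleaner
contrast.

`segment_tissues()` fits a 1-D Gaussian mixture to the in-mask relaxation
values: four components for T1 (WM, GM, partial volume, CSF) or three for
T2 (WM+GM combined — the two are indistinguishable by T2 at this field —
plus partial and CSF). Components are sorted by mean and labeled in that
order, so labels are a deterministic function of the sorted means and the
"partial" bin sits between the parenchyma and CSF, matching its purpose of
absorbing GM/CSF partial-volume voxels. Voxels flagged by the exclusion
rule are removed before fitting. Implementation choices that matter:

* EM is started from the **exact 1-D k-means** solution (dynamic
  programming on a 256-bin weighted histogram, `kmeans1d()`), plus
  quantile and equal-spaced starts and seeded jitters; the converged
  candidate with every component non-vacuous and the highest
  log-likelihood wins. Plain quantile initialization alone is unreliable
  when cluster weights are very unbalanced (CSF is ~14% of brain voxels).
* Component SDs are floored at 1% of the overall data SD, which blocks the
  classic likelihood singularity of a component collapsing onto a few
  near-identical values — a real hazard here because at SNR 95 the
  within-tissue spread of fitted values is very tight.
* Segmentation operates on one axial slice by default (the analysis slice
  is chosen near the ventricles); the functions accept 3-D arrays.

`manual_roi_stats()` averages 2×2 voxel patches, skips excluded voxels,
and — when a segmentation is supplied — enforces the purity rule that a
manual ROI must lie inside a single auto-segmented region.
`tissue_summary()` averages per-subject values per tissue.

# Comparison statistics

`ci95()` returns mean ± 1.96 SD. The replicate counts behind the reported
summaries (3 bench replicates, 6 slices) are small and the source
describes plotting intervals "using the mean and standard deviation", so
no $\sqrt{n}$ or t correction is applied by default; `se_based = TRUE`
provides the t-based variant for sensitivity. Overlap of *closed*
intervals (touching endpoints overlap) defines similarity.
`mean_percent_difference()` uses absolute deviations (the signed mean is
attached as an attribute); whether the original averaged signed or
absolute deviations is unstated. `bland_altman()` normalizes both lists by
the grand mean of all $2n$ values, forms differences `a - b` (pass the
automatic measurements as `a` to match the "automatic minus manual"
convention) and reports the mean difference with ±1.96 SD limits of
agreement.

# Synthetic data: what it does and does not establish

`make_brain_phantom()` builds a concentric-ellipse head — background, a
thin bright skull ring, a dark gap, a GM band, WM interior, two CSF
ventricle lobes, and a one-voxel partial-volume band whose values are
$f \cdot T_{CSF} + (1-f) \cdot T_{GM}$ with $f \sim U(0.25, 0.75)$ — and
simulates the protocol's magnitude signal per voxel with Rician noise.
Default tissue values are the low-field brain values T1 =
0.254/0.377/2.073 s and T2 = 0.081/0.105/1.172 s for WM/GM/CSF; default
SNR is 95 (the value observed in phantom IR scans); in-plane spacing
1.6 mm with 5 mm slices is recorded for realism of voxel counts only. The
geometry is the simplest family that exercises masking, partial volume and
bilateral structure — it is not an anatomical atlas, so a green test
establishes parameter recovery and pipeline correctness, not anatomical
fidelity, registration behavior, or the acquisition physics (FSE echo
trains, spiral k-space, B0/B1 inhomogeneity are all out of scope).

`make_tube_phantom()` lays non-overlapping uniform discs on a grid across
identical slices; default values span the short-T1 (0.1 s) to water-like
(4 s) regime and T2 values extend past ~1.3 s into the regime where the
10-echo imaging schedule (max TE 0.702 s) is known to struggle.
`make_nmr_series()` reproduces the bench spacing rules: 20 exponentially
increasing TIs from $0.001x$ to $x$ (T1), 20 linearly increasing TEs from
$0.05x$ to $x$ (T2), with `suggest_x()` encoding the "largest TI > 5
expected T1" rule and the midpoint (2.75×) of the stated 2.5-3× rule for
T2. All generators are bit-reproducible under a fixed seed.

One negative result is worth stating plainly because the test suite
reports it honestly: with magnitude Rician noise alone at SNR 50, the
10-echo schedule does **not** systematically underestimate a planted
$T_2 = 1.584$ s — a 5000-repeat Monte-Carlo puts the bias at +0.4%
(the Rician floor inflates late echoes). The pronounced long-T2
underestimation observed on the real scanner is attributed by the source
itself to echo-train and system effects that are outside this package's
simulation scope, and the corresponding acceptance test is left failing
rather than weakened. Conversely the short-T2 regime shows the expected
small positive floor bias (+3.6% at SNR 50), comfortably within its 5%
acceptance bound.

# Numerical conventions

Relaxation-time bounds $[10^{-3}, 20]$ s; profiled-fit grid of 48
log-spaced points plus the initialization point; Brent tolerance
$10^{-10}$; EM stopping at relative log-likelihood change $10^{-10}$ with
500 iterations; Otsu threshold on 256 histogram bins; voxel indices are
1-based in R code while circle centers may be fractional; all file times
are seconds. Every stochastic stage consumes a seed derived from a master
seed via a 31-bit hash (`derive_seed()`), so whole-pipeline runs are
reproducible bit for bit.

# Known limitations

* Magnitude-bias-aware (Rician) fitting is deliberately not implemented.
* No multi-exponential or stretched-exponential decay, no B1/flip-angle
  mapping, no atlas-driven segmentation, no inter-session registration.
* The NIfTI reader/writer covers uncompressed little-endian NIfTI-1 with
  scalar datatypes only; contrast times travel in a JSON sidecar.
* The scan-time model is `n_series × seconds_per_series` and does not
  attempt to reproduce scanner bookkeeping beyond that.
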