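# qmrfit

Quantitative T1/T2 relaxometry for low-field MRI: protocol simulation, map
fitting, phantom QA, tissue segmentation, and method-comparison statistics.

## The problem

Portable MRI scanners operating at very low field (tens of mT) make
quantitative imaging attractive for point-of-care use, but accurate tissue
relaxation times (T1, T2) must first be measured at each field strength —
and the measurement protocols themselves must be designed under tight
scan-time budgets and validated against bench NMR references. `qmrfit`
provides that workflow for researchers building or evaluating low-field
relaxometry protocols:

* **Signal models.** Magnitude inversion-recovery signal
  `S = S0 |1 − (1+d) e^(−TI/T1) + e^(−TR/T1)|` with imperfect inversion
  `d` (default 0.95), its full-recovery (`TR ≫ T1`) simplification, the
  monoexponential spin-echo decay `S = S0 e^(−TE/T2)`, and Rician magnitude
  noise (SNR defined as `S0/σ` per channel).
* **Protocol optimization.** Monte-Carlo scoring of candidate TI schedules:
  simulate noisy signals over a T1 grid (default 0.1–4 s) and an SNR sweep,
  refit T1, rank protocols by the bias of the mean estimate under a
  scan-time budget.
* **Map fitting.** Voxel-wise and joint-ROI least squares for T1/T2, with
  Gauss–Newton standard errors and the exclusion rule
  `standard error > estimate` for ill-conditioned long-T1 voxels.
* **Phantom QA.** Hough-transform tube detection, half-radius central ROIs,
  per-slice joint fits, central-six-slice summaries.
* **Brain pipeline.** Threshold–open–close skull stripping, 1-D
  Gaussian-mixture tissue binning (WM/GM/partial/CSF for T1; merged WM+GM
  for T2), 2×2 manual ROIs with a segmentation-purity check.
* **Comparison statistics.** 95% CIs (mean ± 1.96 SD), closed-interval
  overlap, normalization to a reference, mean percent difference, and
  Bland–Altman limits of agreement on grand-mean-normalized values.
* **Synthetic data.** Seed-reproducible digital brain and multi-tube
  phantoms with known ground truth, and bench-style decay series with the
  standard TI/TE spacing rules.

See `vignettes/low-field-relaxometry.Rmd` for the models, assumptions, and
design decisions in detail.

## Worked example

```r
library(qmrfit)

protocol <- ir_protocol_invivo()     # optimized 6-TI schedule, TR 2.4 s
protocol
#> <relax_protocol> inversion_recovery
#>   TI [s]: 0.050, 0.150, 0.350, 0.500, 0.950, 1.995
#>   TR [s]: 2.4   inversion scale d: 0.95

# Monte-Carlo protocol quality: 25 noisy repeats per true T1 at SNR 95
err <- mean_percent_error(protocol, seq(0.1, 4, length.out = 40),
                          snr = 95, n_repeats = 25, seed = 1)
sprintf("mean T1 estimation error at SNR 95: %.2f%%", err)
#> "mean T1 estimation error at SNR 95: 1.56%"

# digital brain phantom -> skull strip -> voxel-wise T1 map -> GMM binning
phantom <- make_brain_phantom(brain_phantom_spec(snr = 95, seed = 1), protocol)
mask <- strip_skull(phantom$series$data[, , 1, 6], source = "raw_image")
map <- reconstruct_map(phantom$series, protocol, mask = as.logical(mask))
seg <- segment_tissues(map, mask, seed = 1)
seg
#> <segmentation_result> t1 mode, 4584 voxels binned
#>   WM       mean 0.254 s  sd 0.00252 s  n 2828
#>   GM       mean 0.377 s  sd 0.0035 s  n 1120
#>   partial  mean 1.241 s  sd 0.233 s  n 116
#>   CSF      mean 2.076 s  sd 0.1 s  n 520
```

The mean error quantifies how well the 6-TI schedule recovers T1 across the
brain-relevant range under realistic noise (~1.5–2%); the segmentation
recovers the planted tissue values (WM 0.254 s, GM 0.377 s, CSF 2.073 s)
from the noisy reconstruction, with the "partial" bin absorbing the mixed
GM/CSF voxels at the ventricle border.

A command-line interface covering the same stages is installed at
`inst/cli/qmrfit` (subcommands `make-phantom`, `optimize-protocol`,
`fit-maps`, `phantom-qa`, `segment`, `compare`, `bland-altman`).

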