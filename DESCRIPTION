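Package: qmrfit
Title: Quantitative MRI Relaxometry at Low Field: Protocol Simulation,
    Map Fitting and Tissue Segmentation
Version: 0.1.0
Authors@R: person("qmrfit", "developers", role = c("aut", "cre"),
    email = "qmrfit@example.org")
Description: Tools for quantitative T1 and T2 relaxometry on low-field
    magnetic resonance images. Provides closed-form inversion-recovery and
    spin-echo magnitude signal models with Rician noise, Monte-Carlo scoring
    and ranking of candidate inversion-time schedules under a scan-time
    budget, voxel-wise and joint region-of-interest least-squares fitting
    with a standard-error exclusion rule, automated phantom-tube detection
    and summaries, skull stripping and Gaussian-mixture tissue binning with
    a partial-volume bin, reference-comparison statistics including
    Bland-Altman limits of agreement, and seed-reproducible digital brain
    and tube phantom generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
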