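# Least-squares T1/T2 fitting, the exclusion rule, map reconstruction and
# joint ROI fits.

test_that("noiseless model-generated signals are recovered exactly", {
  y <- ir_signal(ir_p$times, 0.254, ir_p$tr, 0.95)
  f <- fit_t1(ir_p$times, y, ir_p$tr, 0.95)
  expect_true(f$converged)
  expect_false(f$excluded)
  expect_equal(f$estimate, 0.254, tolerance = 1e-4)
  expect_equal(f$amplitude, 1, tolerance = 1e-4)

  tis <- nmr_tis(5)
  f4 <- fit_t1_full_recovery(tis, ir_signal_full_recovery(tis, 1.0, 0.95), 0.95)
  expect_equal(f4$estimate, 1.0, tolerance = 1e-6)

  f2 <- fit_t2(se_p$times, se_signal(se_p$times, 0.081))
  expect_equal(f2$estimate, 0.081, tolerance = 1e-6)
})

test_that("two-point T2 closed form is reproduced", {
  t <- 0.37
  f <- fit_t2(c(0, t), c(2, 2 / exp(1)))
  expect_equal(f$estimate, t, tolerance = 1e-6)
  expect_equal(f$amplitude, 2, tolerance = 1e-6)
})

test_that("degenerate inputs are refused or flagged", {
  expect_error(fit_t1(c(0.1, 0.2), c(1, 2), tr = 2.4), "3 samples")
  expect_error(fit_t1_full_recovery(c(0.1, 0.2), c(1, 2)), "3 samples")
  expect_error(fit_t2(0.1, 1), "2 samples")
  z <- fit_t1(ir_p$times, rep(0, 6), ir_p$tr)
  expect_false(z$converged)
  expect_true(z$excluded)
  expect_false(fit_t2(c(0.1, 0.2, 0.3), rep(0, 3))$converged)
  # non-decaying data converge but carry a warning flag
  up <- fit_t2(c(0.1, 0.2, 0.3, 0.4), c(1, 1.1, 1.2, 1.3))
  expect_true(up$converged)
  expect_identical(up$warning, "non_decaying")
})

test_that("finite-TR and full-recovery fits agree when TR >> T1", {
  for (t1 in c(0.2, 0.8, 2)) {
    tis <- nmr_tis(5 * t1)
    y <- ir_signal(tis, t1, tr = 20 * t1, d = 0.95)
    a <- fit_t1(tis, y, tr = 20 * t1, d = 0.95)$estimate
    b <- fit_t1_full_recovery(tis, y, d = 0.95)$estimate
    expect_equal(a, b, tolerance = 1e-3)
    # model-mismatch bound at TR = 10 T1 stays below 1%
    y10 <- ir_signal(tis, t1, tr = 10 * t1, d = 0.95)
    expect_equal(fit_t1_full_recovery(tis, y10, d = 0.95)$estimate, t1,
                 tolerance = 0.01)
  }
})

test_that("estimates are invariant to uniform signal rescaling", {
  set.seed(21)
  y <- add_rician_noise(ir_signal(ir_p$times, 0.5, ir_p$tr, 0.95), 0.01)
  f1 <- fit_t1(ir_p$times, y, ir_p$tr, 0.95)
  f2 <- fit_t1(ir_p$times, 1000 * y, ir_p$tr, 0.95)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
  expect_equal(f2$amplitude / f1$amplitude, 1000, tolerance = 1e-6)
  y2 <- add_rician_noise(se_signal(se_p$times, 0.1), 0.01)
  expect_equal(fit_t2(se_p$times, y2)$estimate,
               fit_t2(se_p$times, 250 * y2)$estimate, tolerance = 1e-8)
})

test_that("exclusion flag is exactly standard_error > estimate or no fit", {
  set.seed(31)
  flags_checked <- 0L
  for (i in 1:50) {
    t1 <- runif(1, 0.1, 4)
    y <- add_rician_noise(ir_signal(ir_p$times, t1, ir_p$tr, 0.95), 1 / 10)
    f <- fit_t1(ir_p$times, y, ir_p$tr, 0.95)
    expect_identical(f$excluded,
                     !f$converged || !is.finite(f$standard_error) ||
                       f$standard_error > f$estimate)
    flags_checked <- flags_checked + 1L
  }
  expect_identical(flags_checked, 50L)
})

test_that("long-T1 fits at low SNR are excluded far more often than at high SNR", {
  s <- ir_signal(ir_p$times, 2.073, ir_p$tr, 0.95)
  rate <- function(snr, seed) {
    set.seed(seed)
    mean(replicate(100, fit_t1(ir_p$times, add_rician_noise(s, 1 / snr),
                               ir_p$tr, 0.95)$excluded))
  }
  r95 <- rate(95, 1); r10 <- rate(10, 1)
  expect_lt(r95, 0.01)
  expect_gt(r10, 0.03)
  expect_gt(r10, r95)
})

test_that("reconstruct_map recovers a noiseless phantom and flags background", {
  ph <- small_brain(snr = Inf)
  m <- reconstruct_map(ph$series, ir_p)
  brain <- ph$labels > 1
  expect_lt(max(abs(m$values[brain] - ph$truth$values[brain]) /
                ph$truth$values[brain]), 1e-4)
  expect_false(any(m$exclusion[brain]))
  expect_true(all(m$exclusion[ph$labels == 0]))
  expect_identical(m$kind, "t1")
  # all-background series
  blank <- image_series(array(0, c(4, 4, 1, 6)), ir_p$times)
  mb <- reconstruct_map(blank, ir_p)
  expect_true(all(mb$exclusion))
  # mismatched times
  bad <- image_series(array(1, c(4, 4, 1, 3)), c(0.1, 0.2, 0.3))
  expect_error(reconstruct_map(bad, ir_p), "match")
})

test_that("joint ROI fits pool data correctly", {
  nt <- length(ir_p$times)
  y <- ir_signal(ir_p$times, 0.6, ir_p$tr, 0.95)
  data <- array(rep(y, each = 25), c(5, 5, 1, nt))
  ser <- image_series(data, ir_p$times)
  roi_all <- array(TRUE, c(5, 5, 1))
  joint <- fit_roi_joint(ser, roi_all, ir_p)
  single <- fit_t1(ir_p$times, y, ir_p$tr, 0.95)
  expect_equal(joint$estimate, single$estimate, tolerance = 1e-8)
  expect_error(fit_roi_joint(ser, array(FALSE, c(5, 5, 1)), ir_p), "empty")

  # pooling beats single-voxel precision at SNR 20
  set.seed(41)
  noisy <- array(add_rician_noise(rep(y, each = 100), 1 / 20), c(10, 10, 1, nt))
  sern <- image_series(noisy, ir_p$times)
  jn <- fit_roi_joint(sern, array(TRUE, c(10, 10, 1)), ir_p)
  ses <- apply(matrix(noisy, 100), 1, function(v)
    fit_t1(ir_p$times, v, ir_p$tr, 0.95)$standard_error)
  expect_lt(jn$standard_error, stats::median(ses, na.rm = TRUE))

  # two-tissue ROI lands strictly between the truths
  y2 <- ir_signal(ir_p$times, 1.2, ir_p$tr, 0.95)
  mix <- array(c(rep(y, each = 2), rep(y2, each = 2)), c(2, 2, 1, nt))
  # interleave: first two voxels t1=0.6, last two t1=1.2
  mix <- aperm(array(rbind(matrix(rep(y, each = 2), 2),
                           matrix(rep(y2, each = 2), 2)), c(4, 1, 1, nt)),
               c(1, 2, 3, 4))
  serm <- image_series(mix, ir_p$times)
  fm <- fit_roi_joint(serm, array(TRUE, c(4, 1, 1)), ir_p)
  expect_gt(fm$estimate, 0.6)
  expect_lt(fm$estimate, 1.2)
})
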