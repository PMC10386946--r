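# Signal models, the Rician noise model, and the null-time helper.

test_that("ir_signal matches its closed form and limits", {
  # full-recovery limit: both exponentials vanish
  expect_equal(ir_signal(1e6, t1 = 0.3, tr = 1e7, d = 0.95), 1.0)
  # perfect-inversion null point at T1 log 2 when TR is effectively infinite
  expect_equal(ir_signal(0.5 * log(2), t1 = 0.5, tr = Inf, d = 1), 0)
  # direct high-precision evaluation (independent oracle, frozen)
  expect_equal(ir_signal(0.35, t1 = 0.3, tr = 2.4, d = 0.95),
               abs(1 - 1.95 * exp(-0.35 / 0.3) + exp(-2.4 / 0.3)))
  expect_equal(round(ir_signal(0.35, t1 = 0.3, tr = 2.4, d = 0.95), 4), 0.3931)
  # bounded by the magnitude contract
  ti <- seq(0, 5, by = 0.05)
  s <- ir_signal(ti, t1 = 0.7, tr = 6, d = 0.9, s0 = 2)
  expect_true(all(s >= 0 & s <= 2 * 1.9))
  expect_error(ir_signal(0.1, t1 = -1, tr = 2), "t1")
  expect_error(ir_signal(0.1, t1 = 1, tr = 2, d = 1.2), "d")
})

test_that("full-recovery model is the infinite-TR limit", {
  expect_equal(ir_signal_full_recovery(0, t1 = 0.3, d = 1), 1)  # |1 - 2|
  expect_equal(ir_signal_full_recovery(0.8 * log(1.7), t1 = 0.8, d = 0.7), 0)
  expect_equal(round(ir_signal_full_recovery(0.5, t1 = 0.5, d = 0.95, s0 = 2), 4),
               0.5653)
  set.seed(10)
  for (i in 1:20) {
    t1 <- runif(1, 0.05, 4); ti <- runif(1, 0, 6); d <- runif(1, 0.5, 1)
    expect_equal(ir_signal(ti, t1, tr = 1e9, d = d),
                 ir_signal_full_recovery(ti, t1, d = d), tolerance = 1e-12)
  }
})

test_that("spin-echo signal decays monoexponentially", {
  expect_equal(se_signal(0, t2 = 0.1, s0 = 3), 3)
  expect_equal(se_signal(0.081, t2 = 0.081), exp(-1))
  expect_equal(round(se_signal(0.111, t2 = 0.081), 4), 0.2540)
  te <- seq(0, 1, by = 0.05)
  expect_true(all(diff(se_signal(te, 0.3)) < 0))
  expect_error(se_signal(0.1, t2 = 0), "t2")
})

test_that("Rician noise has the right degenerate, Rayleigh and Rice means", {
  expect_identical(add_rician_noise(c(0, 1, 2), sigma = 0), c(0, 1, 2))
  expect_error(add_rician_noise(1, sigma = -1), "sigma")
  expect_error(add_rician_noise(-1, sigma = 1), "magnitude")
  n <- 1e5
  # Rayleigh mean at zero signal
  draws <- add_rician_noise(rep(0, n), sigma = 1, seed = 42)
  expect_equal(mean(draws), sqrt(pi / 2), tolerance = 3 * 0.66 / sqrt(n))
  expect_true(all(draws >= 0))
  # Rice mean at moderate signal, quadrature oracle
  nu <- 3; sg <- 1
  rice_mean <- stats::integrate(function(r)
    r * r / sg^2 * exp(-(r^2 + nu^2) / (2 * sg^2) + r * nu / sg^2) *
      besselI(r * nu / sg^2, 0, expon.scaled = TRUE),
    0, nu + 12 * sg)$value
  draws <- add_rician_noise(rep(nu, n), sigma = sg, seed = 7)
  expect_equal(mean(draws), rice_mean, tolerance = 3 * sg / sqrt(n))
  # high-SNR expansion: E[m] ~ S + sigma^2 / (2 S)
  s <- 50; draws <- add_rician_noise(rep(s, n), sigma = 1, seed = 8)
  expect_equal(mean(draws), s + 1 / (2 * s), tolerance = 3 / sqrt(n))
})

test_that("Rician draws are reproducible and leave the caller's RNG alone", {
  a <- add_rician_noise(1:5, 0.3, seed = 9)
  b <- add_rician_noise(1:5, 0.3, seed = 9)
  expect_identical(a, b)
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(add_rician_noise(1, 0.5, seed = 4)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ir_null_time is the zero crossing and is monotone in t1", {
  expect_equal(ir_null_time(0.5, tr = Inf, d = 1), 0.5 * log(2))
  expect_equal(round(ir_null_time(0.3, tr = 2.4, d = 0.95), 4), 0.2002)
  set.seed(11)
  for (i in 1:20) {
    t1 <- runif(1, 0.05, 4); tr <- t1 + runif(1, 0.5, 5); d <- runif(1, 0.5, 1)
    expect_lt(ir_signal(ir_null_time(t1, tr, d), t1, tr, d), 1e-10)
  }
  t1s <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(ir_null_time(t1s, tr = 2.4, d = 0.95)) > 0))
})

test_that("protocol and tissue constructors validate their invariants", {
  expect_error(relax_protocol("inversion_recovery", c(0.2, 0.1), 2), "increasing")
  expect_error(relax_protocol("inversion_recovery", c(0.1, 0.2), 0.15), "tr")
  expect_error(relax_protocol("inversion_recovery", c(0.1, 0.2), 2,
                              inversion_scale = 0), "inversion_scale")
  expect_identical(ir_protocol_invivo()$times,
                   c(0.05, 0.15, 0.35, 0.5, 0.95, 1.995))
  expect_identical(length(se_protocol_invivo()$times), 10L)
  expect_identical(length(ir_protocol_reference()$times), 29L)
  expect_warning(tissue_params(t1 = 0.1, t2 = 0.5), "unusual")
  expect_error(tissue_params(t1 = 0), "t1")
})
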