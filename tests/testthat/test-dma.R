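test_that("harmonic least squares recovers amplitude and phase exactly", {
  s <- simulate_dma(E_star = 8, delta = 0.09967, frequency = 1)
  fs <- fit_harmonic(s, "stress")
  fe <- fit_harmonic(s, "strain")
  expect_equal(fe$amplitude, 0.0015, tolerance = 1e-10)
  expect_equal(fs$amplitude, 8 * 0.0015, tolerance = 1e-10)
  expect_equal(fs$phase - fe$phase, 0.09967, tolerance = 1e-10)
  expect_equal(fs$offset, attr(s, "preload_stress"), tolerance = 1e-10)
})

test_that("a linear drift regressor absorbs slow stress drift", {
  s <- simulate_dma(E_star = 8, delta = 0.1, frequency = 1, drift = 0.001)
  # without the drift column the amplitude is contaminated
  amp_plain <- fit_harmonic(s, "stress")$amplitude
  amp_drift <- fit_harmonic(s, "stress", drift = TRUE)$amplitude
  truth <- 8 * 0.0015
  expect_lt(abs(amp_drift - truth) / truth, 0.001)
  expect_gt(abs(amp_plain - truth), abs(amp_drift - truth))
})

test_that("viscoelastic parameters close on the forward model", {
  s <- simulate_dma(E_star = 8, delta = atan(0.100), frequency = 1)
  p <- viscoelastic_params(s)
  expect_equal(p$E_star, 8, tolerance = 1e-8)
  expect_equal(p$tan_delta, 0.100, tolerance = 1e-8)
  # purely elastic: zero phase, zero loss modulus
  s0 <- simulate_dma(E_star = 5, delta = 0, frequency = 1)
  p0 <- viscoelastic_params(s0)
  expect_equal(p0$tan_delta, 0, tolerance = 1e-9)
  expect_equal(p0$E_loss, 0, tolerance = 1e-8)
})

test_that("derived moduli satisfy the complex-modulus identities", {
  for (seed in 1:10) {
    set.seed(seed)
    e <- runif(1, 2, 15)
    d <- runif(1, 0.01, 0.4)
    s <- simulate_dma(E_star = e, delta = d, frequency = 1,
                      noise_sd = 1e-4, seed = seed)
    p <- viscoelastic_params(s)
    expect_equal(p$E_star^2, p$E_storage^2 + p$E_loss^2, tolerance = 1e-12)
    expect_equal(p$tan_delta, p$E_loss / p$E_storage, tolerance = 1e-12)
    expect_equal(p$E_storage, p$E_star * cos(p$delta), tolerance = 1e-12)
    expect_true(p$delta >= 0 && p$delta < pi / 2)
  }
})

test_that("E* and tan delta estimators are nearly unbiased under stress noise", {
  truth_e <- 7
  truth_td <- 0.10
  amp <- 0.0015
  est <- t(vapply(1:500, function(i) {
    s <- simulate_dma(E_star = truth_e, delta = atan(truth_td), frequency = 1,
                      strain_amplitude = amp,
                      noise_sd = 0.02 * truth_e * amp, seed = 2000 + i)
    p <- viscoelastic_params(s)
    c(p$E_star, p$tan_delta)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - truth_e) / truth_e, 0.005)
  expect_lt(abs(mean(est[, 2]) - truth_td), 0.005)
})

test_that("the frequency x preload sweep recovers every cell and flags the reference", {
  co <- generate_cohort(2, 1, seed = 42)
  truth <- co[1, ]
  b <- render_raw_records(truth, seed = 5)
  sweep <- run_dma_sweep(b$dma)
  expect_equal(nrow(sweep), 12)
  expect_equal(sum(sweep$reference), 1)
  ref <- sweep[sweep$reference, ]
  expect_equal(ref$E_star, truth$E_star, tolerance = 1e-6)
  expect_equal(ref$tan_delta, truth$tan_delta, tolerance = 1e-6)
  # monotone frequency dependence and preload direction as generated
  for (p in c(0.04, 0.1)) {
    e_col <- sweep$E_star[sweep$preload == p][order(sweep$frequency[sweep$preload == p])]
    expect_true(all(diff(e_col) > 0))
  }
  at1 <- sweep[sweep$frequency == 1, ]
  expect_gt(at1$E_star[at1$preload == 0.1], at1$E_star[at1$preload == 0.04])
  expect_lt(at1$tan_delta[at1$preload == 0.1], at1$tan_delta[at1$preload == 0.04])
  # missing cell reported as NA, not imputed
  sweep2 <- run_dma_sweep(b$dma[-1])
  expect_equal(sum(is.na(sweep2$E_star)), 1)
})

test_that("Laplace hoop stress matches the generic-globe preload rationale", {
  expect_equal(laplace_preload_stress(15, 12, 0.5), 0.023998, tolerance = 1e-4)
  # doubling thickness halves stress; pressure ratio carries through
  expect_equal(laplace_preload_stress(15, 12, 1.0),
               laplace_preload_stress(15, 12, 0.5) / 2)
  expect_equal(laplace_preload_stress(35, 12, 0.5) /
                 laplace_preload_stress(15, 12, 0.5), 35 / 15)
})

test_that("amplitudes above the linearity bound are flagged", {
  s <- simulate_dma(E_star = 8, delta = 0.1, strain_amplitude = 0.003)
  expect_true(attr(s, "nonlinear_warning"))
  s2 <- simulate_dma(E_star = 8, delta = 0.1, strain_amplitude = 0.0015)
  expect_false(attr(s2, "nonlinear_warning"))
})
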