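test_that("every generator is bitwise deterministic under a fixed seed", {
  truth <- hn_truth_asym(1e-10)
  fg <- freq_grid_decades(1e-2, 1e6, 13)
  expect_identical(sim_hn_spectrum(truth, fg, 0.05, seed = 42),
                   sim_hn_spectrum(truth, fg, 0.05, seed = 42))
  expect_identical(sim_ri_crystallization(seed = 42),
                   sim_ri_crystallization(seed = 42))
  expect_identical(sim_ri_cooling(seed = 42), sim_ri_cooling(seed = 42))
  expect_identical(sim_dsc_trace(noise_sd = 1e-3, seed = 42),
                   sim_dsc_trace(noise_sd = 1e-3, seed = 42))
  expect_identical(sim_onset_table(nucl_temps, -19.9, 171, 0.1, seed = 42),
                   sim_onset_table(nucl_temps, -19.9, 171, 0.1, seed = 42))
  # different seeds differ
  expect_false(identical(sim_ri_cooling(seed = 1), sim_ri_cooling(seed = 2)))
  # generators leave the global RNG untouched
  withr::with_seed(7, {
    before <- .Random.seed
    invisible(sim_hn_spectrum(truth, fg, 0.05, seed = 42))
    expect_identical(.Random.seed, before)
  })
})

test_that("noisy generators demand an explicit seed", {
  truth <- hn_truth_asym()
  expect_error(sim_hn_spectrum(truth, freq_grid_decades(), 0.01), "seed")
  expect_error(sim_ri_crystallization(noise_sd = 1e-4), "seed")
  expect_error(sim_onset_table(nucl_temps, -19.9, 171, 0.1), "seed")
})

test_that("noiseless generator output composed with each estimator recovers the truth", {
  # HN spectrum -> fit_hn
  truth <- hn_truth_asym(1e-10)
  hn_est <- fit_hn(sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 13)))
  for (nm in c("sigma0", "eps_inf", "delta_eps", "tau_alpha", "xi", "delta")) {
    expect_lt(rel_err(hn_est$params[[nm]], truth[[nm]]), 1e-6)
  }
  # VFT series -> fit_vft
  vtruth <- vft_etb_30()
  vest <- fit_vft(sim_relaxation_series(vtruth, seq(330, 380, length.out = 12)))
  expect_lt(rel_err(vest$A, vtruth$A), 1e-6)
  # Arrhenius table -> fit_nucleation_arrhenius
  nest <- fit_nucleation_arrhenius(sim_onset_table(nucl_temps, -19.9, 171))
  expect_lt(rel_err(nest$e_nucl_kj_mol, 171), 1e-6)
  # bilinear scan -> tg_from_bilinear
  best <- tg_from_bilinear(sim_ri_cooling(noise_sd = 0))
  expect_lt(rel_err(best$tg_k, 327), 1e-6)
  # DSC step -> tg_from_dsc_step
  dest <- tg_from_dsc_step(sim_dsc_trace(noise_sd = 0))
  expect_lt(rel_err(dest$tg_k, 330), 1e-6)
})

test_that("simulated loss is positive and eps_real decreases with frequency", {
  withr::with_seed(3, {
    for (i in 1:10) {
      xi <- runif(1, 0.4, 1)
      truth <- hn_params(delta_eps = 10^runif(1, -1, 1.5),
                         tau_alpha = 10^runif(1, -5, 0),
                         xi = xi, delta = runif(1, 0.3, 1 / xi),
                         sigma0 = 0, eps_inf = runif(1, 2, 5))
      sp <- sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 10))
      expect_true(all(sp$eps_imag > 0))
      expect_true(all(diff(sp$eps_real) <= 1e-12))
    }
  })
})

test_that("simulated HN spectra peak where the closed form says they should", {
  truth <- hn_truth_asym(0) # no dc tail: the loss maximum is the HN peak
  sp <- sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 13))
  f_obs <- sp$frequency_hz[which.max(sp$eps_imag)]
  # closed-form peak, to grid resolution (1/13 decade)
  expect_lt(abs(log10(f_obs) - log10(hn_peak_frequency(truth))), 1 / 13)
})

test_that("the VFT series generator matches direct evaluation", {
  # constant-timescale degenerate case
  flat <- sim_relaxation_series(vft_params(-5, 0, 100), c(300, 350, 400))
  expect_equal(flat$tau_alpha_s, rep(1e-5, 3))

  # published pure-excipient parameters at 338 K, by hand
  got <- sim_relaxation_series(vft_acmal(), 338)$tau_alpha_s
  expect_equal(log10(got), -12.3 + 1400 / (log(10) * 53), tolerance = 1e-12)

  # supercooled-drug parameters reach 100 s near 328.06 K
  expect_equal(sim_relaxation_series(vft_etb(), 328.06)$tau_alpha_s, 100,
               tolerance = 0.01)

  expect_error(sim_relaxation_series(vft_etb(), 260), "T_VFT")
})

test_that("the onset-table generator matches the Arrhenius law by hand", {
  # zero energy: constant onset time
  flat <- sim_onset_table(c(350, 370, 390), 3, 0)
  expect_equal(flat$t_onset_s, rep(1000, 3))
  # printed drug parameters at 368 K: about 2.4e4 s (about 6 h)
  got <- sim_onset_table(368, -19.9, 171)$t_onset_s
  expect_equal(got, 2.36e4, tolerance = 0.005)
})

test_that("crystallization trace morphology: linear drift, max at onset, Avrami drop", {
  tr <- sim_ri_crystallization(time_s = seq(0, 10000, by = 5),
                               t_onset_true = 5000, noise_sd = 0)
  ri <- tr$refractive_index
  pre <- tr$time_s <= 5000
  expect_equal(which.max(ri), max(which(pre))) # global max at the onset
  expect_equal(diff(ri[pre]), rep(1e-7 * 5, sum(pre) - 1), tolerance = 1e-6)
  post <- tr$time_s > 5000
  dt <- tr$time_s[post] - 5000
  expected_post <- ri[max(which(pre))] - 0.01 * (1 - exp(-6e-8 * dt^2))
  expect_equal(ri[post], expected_post, tolerance = 1e-12)

  expect_error(sim_ri_crystallization(time_s = c(0, 10, 5)), "ascending")
})

test_that("cooling-scan generator is piecewise linear with the stated break", {
  tr <- sim_ri_cooling(temperature_k = seq(360, 300, by = -1), tg_true = 330,
                       noise_sd = 0)
  liq <- tr$temperature_k >= 330
  fit_liq <- lm(refractive_index ~ temperature_k, data = tr[liq, ])
  fit_gls <- lm(refractive_index ~ temperature_k, data = tr[!liq, ])
  expect_equal(unname(coef(fit_liq)[2]), -4e-4, tolerance = 1e-10)
  expect_equal(unname(coef(fit_gls)[2]), -1.5e-4, tolerance = 1e-10)
})
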