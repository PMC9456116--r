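test_that("HN model reduces to the Debye form at xi = delta = 1", {
  p <- hn_params(delta_eps = 1, tau_alpha = 1 / (2 * pi), xi = 1, delta = 1,
                 eps_inf = 2)
  at_peak <- hn_loss(1, p)
  expect_equal(at_peak$eps_imag, 0.5, tolerance = 1e-12)
  expect_equal(at_peak$eps_real, 2.5, tolerance = 1e-12)

  # agreement with the explicit Debye expression across frequencies
  f <- 10^seq(-3, 3, length.out = 61)
  got <- hn_loss(f, p)
  z <- 1 / (1 + 1i * 2 * pi * f * p$tau_alpha)
  expect_equal(got$eps_real, p$eps_inf + Re(z), tolerance = 1e-12)
  expect_equal(got$eps_imag, -Im(z), tolerance = 1e-12)
})

test_that("conductivity dominates the low-frequency loss with slope -1", {
  p <- hn_params(delta_eps = 3, tau_alpha = 1e-3, xi = 0.85, delta = 0.6,
                 sigma0 = 1e-8, eps_inf = 3)
  f <- c(1e-4, 1e-3)
  l <- hn_loss(f, p)
  dc <- p$sigma0 / (2 * pi * f * physical_constants()$eps0)
  expect_equal(l$eps_imag, dc, tolerance = 1e-3)
  slope <- diff(log10(l$eps_imag)) / diff(log10(f))
  expect_equal(slope, -1, tolerance = 1e-3)

  # degenerate relaxation: zero strength, zero conductivity
  p0 <- hn_params(delta_eps = 0, tau_alpha = 1, xi = 1, delta = 1,
                  eps_inf = 4)
  l0 <- hn_loss(c(0.1, 10), p0)
  expect_equal(l0$eps_real, c(4, 4))
  expect_equal(l0$eps_imag, c(0, 0))

  expect_error(hn_loss(c(-1, 1), p), "positive")
})

test_that("closed-form peak frequency matches a dense-grid argmax", {
  p <- hn_params(delta_eps = 3, tau_alpha = 1e-3, xi = 0.85, delta = 0.6,
                 eps_inf = 3)
  fg <- 10^seq(-1, 6, length.out = 70001) # 1e-4 decades resolution
  loss <- hn_loss(fg, p)
  f_grid <- fg[which.max(loss$eps_imag)]
  expect_equal(log10(hn_peak_frequency(p)), log10(f_grid), tolerance = 2e-4)
})

test_that("single-process loss is unimodal for random physical parameters", {
  withr::with_seed(11, {
    for (i in 1:20) {
      xi <- runif(1, 0.3, 1)
      delta <- runif(1, 0.2, 1 / xi)
      p <- hn_params(delta_eps = 10^runif(1, -1, 2),
                     tau_alpha = 10^runif(1, -6, 1),
                     xi = xi, delta = delta, eps_inf = 2)
      fg <- 10^seq(log10(hn_peak_frequency(p)) - 5,
                   log10(hn_peak_frequency(p)) + 5, length.out = 2000)
      loss <- hn_loss(fg, p)$eps_imag
      expect_true(all(loss > 0))
      n_flips <- sum(diff(sign(diff(loss))) != 0)
      expect_lte(n_flips, 1) # one maximum, no secondary extrema
    }
  })
})

test_that("noiseless spectra round-trip through fit_hn to 1e-6 relative", {
  for (sigma0 in c(0, 1e-10)) {
    truth <- hn_truth_asym(sigma0)
    sp <- sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 13),
                          noise_rel = 0)
    fit <- fit_hn(sp)
    expect_true(fit$converged)
    for (nm in c("eps_inf", "delta_eps", "tau_alpha", "xi", "delta")) {
      expect_lt(rel_err(fit$params[[nm]], truth[[nm]]), 1e-6)
    }
    if (sigma0 > 0) expect_lt(rel_err(fit$params$sigma0, sigma0), 1e-6)
  }
})

test_that("fitted shape parameters are invariant to a uniform loss rescaling", {
  truth <- hn_truth_asym(1e-10)
  sp <- sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 13), noise_rel = 0)
  scaled <- dplyr::mutate(sp, eps_imag = eps_imag * 37,
                          eps_real = NA_real_)
  f1 <- fit_hn(dplyr::mutate(sp, eps_real = NA_real_))
  f2 <- fit_hn(scaled)
  expect_lt(rel_err(f2$params$tau_alpha, f1$params$tau_alpha), 1e-8)
  expect_lt(abs(f2$params$xi - f1$params$xi), 1e-8)
  expect_lt(abs(f2$params$delta - f1$params$delta), 1e-8)
  expect_lt(rel_err(f2$params$delta_eps, 37 * f1$params$delta_eps), 1e-8)
  expect_lt(rel_err(f2$params$sigma0, 37 * f1$params$sigma0), 1e-8)
})

test_that("conductivity does not bias the fitted relaxation time", {
  truth_clean <- hn_truth_asym(0)
  truth_cond <- hn_truth_asym(5e-10)
  f1 <- fit_hn(sim_hn_spectrum(truth_clean, freq_grid_decades(1e-2, 1e6, 13)))
  f2 <- fit_hn(sim_hn_spectrum(truth_cond, freq_grid_decades(1e-2, 1e6, 13)))
  dl <- abs(log10(f1$params$tau_alpha) - log10(f2$params$tau_alpha))
  expect_lt(dl, max(1e-8, 2 * (f1$tau_se_log10 + f2$tau_se_log10)))
})

test_that("relaxation time survives 1% multiplicative loss noise", {
  truth <- hn_truth_asym(1e-10)
  errs <- vapply(1:50, function(s) {
    sp <- sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 13),
                          noise_rel = 0.01, seed = 1000 + s)
    f <- fit_hn(sp)
    abs(log10(f$params$tau_alpha) - log10(truth$tau_alpha))
  }, 0)
  expect_lt(median(errs), 0.02)
})

test_that("fit_hn rejects pathological inputs", {
  truth <- hn_truth_asym(0)
  sp <- sim_hn_spectrum(truth, freq_grid_decades(1, 1e4, 13))
  expect_error(fit_hn(sp[7:1, ]), "ascending")
  expect_error(fit_hn(sp[1:5, ]), "8")
  # monotone flank only, no interior peak, no init: cannot initialize
  flank <- sim_hn_spectrum(hn_params(delta_eps = 3, tau_alpha = 10, xi = 0.9,
                                     delta = 0.8, eps_inf = 3),
                           freq_grid_decades(1e2, 1e5, 5))
  expect_error(fit_hn(dplyr::select(flank, -eps_real)), "un-initializable")
  # but an explicit init rescues the same spectrum
  expect_s3_class(fit_hn(flank, init = hn_params(3, 10, 0.9, 0.8, 0, 3)),
                  "hn_fit")
})

test_that("build_relaxation_map composes, filters and sorts correctly", {
  vft <- vft_etb()
  temps <- seq(338, 378, by = 8)
  truth_map <- sim_relaxation_series(vft, temps)
  fits <- lapply(seq_along(temps), function(i) {
    truth <- hn_params(delta_eps = 3,
                       tau_alpha = truth_map$tau_alpha_s[i],
                       xi = 0.85, delta = 0.6, eps_inf = 3)
    fit_hn(sim_hn_spectrum(truth, freq_grid_decades(1e-2, 1e6, 13),
                           temperature_k = temps[i]))
  })
  map <- build_relaxation_map(fits)
  expect_equal(nrow(map), length(temps))
  # coldest first (descending 1/T)
  expect_equal(map$temperature_k, sort(temps))
  expect_equal(log10(map$tau_alpha_s),
               log10(sort(truth_map$tau_alpha_s, decreasing = TRUE)),
               tolerance = 1e-6)

  # single fit -> single row
  expect_equal(nrow(build_relaxation_map(fits[[1]])), 1)

  # a non-converged entry is excluded with a warning
  fits[[2]]$converged <- FALSE
  expect_warning(map2 <- build_relaxation_map(fits), "non-converged")
  expect_equal(nrow(map2), length(temps) - 1)
  expect_error(build_relaxation_map(list()), "no fits")
})
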