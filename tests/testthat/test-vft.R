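published_vft_rows <- list(
  pure_etb = vft_etb(), etb_20 = vft_etb_20(), etb_30 = vft_etb_30(),
  etb_40 = vft_etb_40(), etb_50 = vft_etb_50(), pure_acmal = vft_acmal()
)

test_that("noiseless VFT series refit to the generating parameters", {
  for (nm in names(published_vft_rows)) {
    truth <- published_vft_rows[[nm]]
    map <- sim_relaxation_series(truth, seq(330, 380, length.out = 12))
    fit <- fit_vft(map)
    expect_true(fit$converged)
    expect_lt(rel_err(fit$log10_tau0, truth$log10_tau0), 1e-6)
    expect_lt(rel_err(fit$A, truth$A), 1e-6)
    expect_lt(rel_err(fit$T_VFT, truth$T_VFT), 1e-6)
  }
})

test_that("data generated without a Vogel temperature fit as Arrhenius", {
  truth <- vft_params(-10, 4000, 0)
  map <- sim_relaxation_series(truth, seq(250, 400, length.out = 15))
  fit <- fit_vft(map)
  se_tv <- sqrt(fit$covariance["T_VFT", "T_VFT"])
  expect_lt(fit$T_VFT, max(1e-3, 2 * se_tv))
  expect_lt(rel_err(fit$A, truth$A), 1e-3)
})

test_that("fit_vft guards its preconditions and extrapolation validity", {
  truth <- vft_etb()
  map <- sim_relaxation_series(truth, seq(338, 378, length.out = 12))
  expect_error(fit_vft(map[1:3, ]), "at least 4")
  shallow <- sim_relaxation_series(truth, seq(370, 378, length.out = 6))
  expect_error(fit_vft(shallow), "2 decades")
  dup <- dplyr::bind_rows(map, map[1, ])
  expect_error(fit_vft(dup), "unique")

  # Vogel temperature hugging the coldest datum: convergence refused
  close_truth <- vft_params(-3, 3, 330.4)
  close_map <- sim_relaxation_series(close_truth, seq(331, 345, by = 1))
  expect_warning(cfit <- fit_vft(close_map), "within 1 K")
  expect_false(cfit$converged)
})

test_that("closed-form Tg inversion agrees with a root-solve of the VFT law", {
  for (vft in list(vft_etb(), vft_acmal(), vft_etb_50())) {
    tg <- tg_at_timescale(vft, 100)$tg_k
    expect_equal(tg, root_tg(vft, 100), tolerance = 1e-8)
  }
  expect_equal(tg_at_timescale(vft_etb())$tg_k, 328.1, tolerance = 1e-3)
  expect_equal(tg_at_timescale(vft_acmal())$tg_k, 327.5, tolerance = 1e-3)

  expect_error(tg_at_timescale(vft_etb(), tau_ref = 1e-18), "exceed tau0")
  expect_error(tg_at_timescale(vft_params(-16.8, 0, 265)), "undefined")
})

test_that("closed-form fragility equals the numeric steepness-index derivative", {
  withr::with_seed(5, {
    for (i in 1:25) {
      vft <- vft_params(runif(1, -20, -8), runif(1, 500, 5000),
                        runif(1, 100, 300))
      tg <- tg_at_timescale(vft)$tg_k
      m <- isobaric_fragility(vft, tg)
      expect_lt(rel_err(m, numeric_fragility(vft, tg)), 1e-6)
    }
  })
  expect_equal(isobaric_fragility(vft_etb()), 98, tolerance = 0.01)
  expect_equal(isobaric_fragility(vft_acmal()), 110, tolerance = 0.01)
})

test_that("the Arrhenius limit yields the minimal-fragility identity", {
  vft <- vft_params(-14, 4000, 0)
  tg <- tg_at_timescale(vft)$tg_k
  m <- isobaric_fragility(vft, tg)
  expect_equal(m, vft$A / (log(10) * tg), tolerance = 1e-10)
  expect_equal(m, log10(tau_vft(tg, vft)) - vft$log10_tau0, tolerance = 1e-6)
})

test_that("fragility classification applies closed boundaries", {
  expect_equal(classify_fragility(c(10, 30, 30.001, 98, 99.999, 100, 110)),
               c("strong", "strong", "moderately fragile", "moderately fragile",
                 "moderately fragile", "fragile", "fragile"))
  expect_error(classify_fragility(-1), "positive")
})

test_that("windowed Arrhenius energy matches the local VFT derivative oracle", {
  vft <- vft_etb()
  # local activation energy R * A * T^2 / (T - T_VFT)^2 at the window midpoint
  mid <- 367.15
  local_e <- physical_constants()$R * vft$A * mid^2 /
    (mid - vft$T_VFT)^2 / 1000
  ea <- apparent_activation_energy(vft, c(361.15, 373.15))
  expect_equal(ea$e_alpha_kj_mol, local_e, tolerance = 0.005)

  # shrinking window converges to the exact local derivative
  for (hw in c(2, 0.5, 0.05)) {
    e <- apparent_activation_energy(vft, c(mid - hw, mid + hw))$e_alpha_kj_mol
    expect_equal(e, local_e, tolerance = max(1e-6, (hw / mid)^2 * 100))
  }

  # pure Arrhenius input: energy A*R, independent of the window
  arr <- vft_params(-10, 1000, 0)
  e1 <- apparent_activation_energy(arr, c(250, 300))$e_alpha_kj_mol
  e2 <- apparent_activation_energy(arr, c(350, 420))$e_alpha_kj_mol
  expect_equal(e1, 8.314, tolerance = 1e-9)
  expect_equal(e2, 8.314, tolerance = 1e-9)

  expect_error(apparent_activation_energy(vft, c(373, 361)), "T_low < T_high")
  expect_error(apparent_activation_energy(vft, c(260, 300)), "T_VFT")
})

test_that("windowed energy is bracketed by the edge-implied Arrhenius energies", {
  withr::with_seed(21, {
    for (i in 1:10) {
      vft <- vft_params(runif(1, -18, -10), runif(1, 1000, 4000),
                        runif(1, 200, 280))
      lo <- vft$T_VFT + runif(1, 40, 80)
      hi <- lo + runif(1, 5, 30)
      e_edge <- function(T_) {
        physical_constants()$R * vft$A * T_^2 / (T_ - vft$T_VFT)^2 / 1000
      }
      e <- apparent_activation_energy(vft, c(lo, hi))$e_alpha_kj_mol
      expect_gte(e, e_edge(hi) - 1e-9)
      expect_lte(e, e_edge(lo) + 1e-9)
    }
  })
})

test_that("map-mode energy uses the raw in-window points", {
  vft <- vft_etb()
  map <- sim_relaxation_series(vft, seq(356, 378, by = 2))
  ea_map <- apparent_activation_energy(map, c(361, 373.5), source = "map")
  ea_vft <- apparent_activation_energy(vft, c(361, 373.5))
  expect_equal(ea_map$e_alpha_kj_mol, ea_vft$e_alpha_kj_mol, tolerance = 0.01)
  expect_error(apparent_activation_energy(map[1:2, ], c(356, 378),
                                          source = "map"), "fewer than 3")
})

test_that("noisy VFT fits recover the truth within 2 standard errors", {
  truth <- vft_etb()
  temps <- seq(338, 378, length.out = 15)
  hits <- vapply(1:200, function(s) {
    map <- sim_relaxation_series(truth, temps, noise_log_sd = 0.05,
                                 seed = 40000 + s)
    fit <- fit_vft(map)
    se <- sqrt(pmax(diag(fit$covariance), 1e-20))
    all(abs(c(fit$log10_tau0 - truth$log10_tau0,
              fit$A - truth$A,
              fit$T_VFT - truth$T_VFT)) <= 2 * se)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("fragility_report assembles the dynamic summary", {
  rep <- fragility_report(fit_vft(sim_relaxation_series(
    vft_etb(), seq(330, 380, length.out = 12))),
    e_alpha_window = c(361.15, 373.15))
  expect_equal(rep$tg_dielectric_k, 328.07, tolerance = 1e-3)
  expect_equal(rep$class_label, "moderately fragile")
  expect_equal(rep$e_alpha_kj_mol, 293.8, tolerance = 0.01)
})
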