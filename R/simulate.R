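#' Simulate a dielectric spectrum from known HN ground truth
#'
#' Evaluates the HN + dc-conductivity model on a frequency grid and
#' optionally perturbs the loss with multiplicative lognormal noise (the
#' loss spans decades, so relative noise is the natural model). The real
#' part is left noiseless; with `noise_rel = 0` the output is exactly the
#' model. Identical `seed` and inputs give bitwise-identical output; the
#' global random state is untouched.
#'
#' @param truth An [hn_params()] object (the ground truth).
#' @param frequency_hz Positive, ascending frequency grid (Hz).
#' @param noise_rel Relative noise fraction on the loss (lognormal sdlog);
#'   >= 0.
#' @param seed Integer seed (required when `noise_rel > 0`).
#' @param temperature_k Optional temperature metadata carried in a column.
#' @return Tibble: `temperature_k` (if given), `frequency_hz`, `eps_real`,
#'   `eps_imag`.
#' @export
#' @examples
#' p <- hn_params(delta_eps = 3, tau_alpha = 1e-3, xi = 0.85, delta = 0.6,
#'                sigma0 = 1e-10, eps_inf = 3)
#' sim_hn_spectrum(p, freq_grid_decades(1e-2, 1e6), noise_rel = 0)
sim_hn_spectrum <- function(truth, frequency_hz, noise_rel = 0, seed = NULL,
                            temperature_k = NULL) {
  stopifnot(inherits(truth, "hn_params"))
  if (any(frequency_hz <= 0) || is.unsorted(frequency_hz, strictly = TRUE)) {
    abort("`frequency_hz` must be positive and strictly ascending.")
  }
  check_scalar(noise_rel, "noise_rel", lower = 0)
  out <- hn_loss(frequency_hz, truth)
  if (noise_rel > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_rel` > 0.")
    out$eps_imag <- withr::with_seed(seed, {
      out$eps_imag * exp(rnorm(nrow(out), 0, noise_rel))
    })
  }
  if (!is.null(temperature_k)) {
    out <- dplyr::mutate(out, temperature_k = temperature_k, .before = 1)
  }
  out
}

#' Logarithmic frequency grid
#'
#' @param from,to Grid limits (Hz), `from < to`, both positive.
#' @param points_per_decade Grid density (default 13).
#' @return Ascending frequency vector.
#' @export
freq_grid_decades <- function(from = 1e-2, to = 1e6, points_per_decade = 13) {
  stopifnot(from > 0, to > from)
  10^seq(log10(from), log10(to),
         by = 1 / points_per_decade)
}

#' Simulate a relaxation-time series from VFT parameters
#'
#' Exact (noiseless by default) evaluation of
#' \eqn{\tau_\alpha(T) = \tau_0\exp(A/(T - T_{VFT}))}, optionally with
#' Gaussian noise in \eqn{\log_{10}\tau} space.
#'
#' @param vft A [vft_params()] object.
#' @param temperature_k Temperatures (K), all above `T_VFT`.
#' @param noise_log_sd SD of Gaussian noise in log10 space (decades).
#' @param seed Integer seed (required when noisy).
#' @return Tibble: `temperature_k`, `tau_alpha_s`.
#' @export
#' @examples
#' etb <- vft_params(-16.8, 2730, 265)
#' sim_relaxation_series(etb, seq(338, 378, by = 4))
sim_relaxation_series <- function(vft, temperature_k, noise_log_sd = 0,
                                  seed = NULL) {
  tau <- tau_vft(temperature_k, vft)
  if (noise_log_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_log_sd` > 0.")
    tau <- withr::with_seed(seed, {
      10^(log10(tau) + rnorm(length(tau), 0, noise_log_sd))
    })
  }
  tibble(temperature_k = temperature_k, tau_alpha_s = tau)
}

#' Simulate an isothermal refractometry crystallization trace
#'
#' Emulates the refractive-index-versus-time morphology of an isothermal
#' crystallization experiment: a slow linear densification drift up to the
#' ground-truth onset time, followed by an Avrami-type drop
#' \eqn{\Delta RI\,[1 - \exp(-k (t - t_{onset})^n)]} as the transformation
#' proceeds. With zero noise the global maximum of the trace sits exactly at
#' `t_onset_true`. Defaults emulate a supercooled melt held near 368 K:
#' a 22 h experiment sampled every 10 s, onset near 6 h, RI around 1.53 with
#' instrument-level noise.
#'
#' @param time_s Ascending time grid starting at 0 (s).
#' @param t_onset_true Ground-truth onset time (s), > 0; set `Inf` for a
#'   non-crystallizing (stable) run.
#' @param temperature_k Temperature metadata (K).
#' @param ri_start Initial refractive index.
#' @param drift_rate Pre-onset drift (RI/s).
#' @param ri_drop Total RI drop amplitude, > 0.
#' @param kinetic_rate Post-onset transformation rate (1/s^n).
#' @param avrami_n Transformation exponent, > 0.
#' @param noise_sd Additive Gaussian noise SD (RI units), >= 0.
#' @param seed Integer seed (required when noisy).
#' @return Tibble: `temperature_k`, `time_s`, `refractive_index`.
#' @export
sim_ri_crystallization <- function(time_s = seq(0, 22 * 3600, by = 10),
                                   t_onset_true = 6 * 3600,
                                   temperature_k = 368,
                                   ri_start = 1.53,
                                   drift_rate = 1e-7,
                                   ri_drop = 0.01,
                                   kinetic_rate = 6e-8,
                                   avrami_n = 2,
                                   noise_sd = 5e-5,
                                   seed = NULL) {
  if (is.unsorted(time_s, strictly = TRUE) || time_s[1] < 0) {
    abort("`time_s` must be strictly ascending and start at >= 0.")
  }
  if (!identical(t_onset_true, Inf)) {
    check_scalar(t_onset_true, "t_onset_true", lower = 0, strict_lower = TRUE)
  }
  check_scalar(ri_drop, "ri_drop", lower = 0)
  check_scalar(avrami_n, "avrami_n", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  ri <- ri_start + drift_rate * pmin(time_s, t_onset_true)
  post <- time_s > t_onset_true
  if (any(post)) {
    dt <- time_s[post] - t_onset_true
    ri[post] <- ri[post] - ri_drop * (1 - exp(-kinetic_rate * dt^avrami_n))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_sd` > 0.")
    ri <- withr::with_seed(seed, ri + rnorm(length(ri), 0, noise_sd))
  }
  tibble(temperature_k = temperature_k, time_s = time_s,
         refractive_index = ri)
}

#' Simulate a bilinear refractive-index cooling scan
#'
#' Piecewise-linear RI(T) with a slope break at the ground-truth Tg: the
#' liquid branch above, the glass branch below, continuous at the break.
#' Default slopes are typical refractometric values for an organic melt
#' (the liquid densifies faster with temperature than the glass).
#'
#' @param temperature_k Temperature grid (K), descending for a cooling scan
#'   (any monotone order accepted).
#' @param tg_true Breakpoint temperature (K).
#' @param slope_liquid,slope_glass RI-vs-T slopes (1/K) above/below Tg; must
#'   differ for a detectable transition.
#' @param ri_at_tg RI at the breakpoint.
#' @param noise_sd Additive Gaussian noise SD, >= 0.
#' @param seed Integer seed (required when noisy).
#' @return Tibble: `temperature_k`, `refractive_index`.
#' @export
sim_ri_cooling <- function(temperature_k = seq(368, 303, length.out = 200),
                           tg_true = 327,
                           slope_liquid = -4e-4,
                           slope_glass = -1.5e-4,
                           ri_at_tg = 1.545,
                           noise_sd = 1e-4,
                           seed = NULL) {
  check_scalar(tg_true, "tg_true", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  ri <- ifelse(temperature_k >= tg_true,
               ri_at_tg + slope_liquid * (temperature_k - tg_true),
               ri_at_tg + slope_glass * (temperature_k - tg_true))
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_sd` > 0.")
    ri <- withr::with_seed(seed, ri + rnorm(length(ri), 0, noise_sd))
  }
  tibble(temperature_k = temperature_k, refractive_index = ri)
}

#' Simulate a DSC heating trace with a glass-transition step
#'
#' Linear baseline plus a smooth logistic step of the stated height centered
#' at the ground-truth Tg; the conventional midpoint construction recovers
#' `tg_true` exactly on noiseless output. The default step height
#' corresponds to a heat-capacity jump of ~0.35 J/(g K) scanned at
#' 10 K/min.
#'
#' @param temperature_k Ascending temperature grid (K).
#' @param tg_true Step center (K).
#' @param step_height Heat-flow jump (W/g), >= 0.
#' @param width Step width parameter (K); the 10-90% rise spans about
#'   4.4 x `width`.
#' @param heating_rate_k_min Heating rate metadata (K/min).
#' @param baseline_level,baseline_slope Linear baseline (W/g, W/(g K)).
#' @param noise_sd Additive Gaussian noise SD (W/g), >= 0.
#' @param seed Integer seed (required when noisy).
#' @return Tibble: `temperature_k`, `heat_flow`, `heating_rate_k_min`.
#' @export
sim_dsc_trace <- function(temperature_k = seq(300, 360, by = 0.25),
                          tg_true = 330,
                          step_height = 0.06,
                          width = 2,
                          heating_rate_k_min = 10,
                          baseline_level = 0.2,
                          baseline_slope = 0,
                          noise_sd = 0,
                          seed = NULL) {
  if (is.unsorted(temperature_k, strictly = TRUE)) {
    abort("`temperature_k` must be strictly ascending.")
  }
  check_scalar(step_height, "step_height", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  hf <- baseline_level + baseline_slope * (temperature_k - tg_true) +
    step_height / (1 + exp(-(temperature_k - tg_true) / width))
  if (noise_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_sd` > 0.")
    hf <- withr::with_seed(seed, hf + rnorm(length(hf), 0, noise_sd))
  }
  tibble(temperature_k = temperature_k, heat_flow = hf,
         heating_rate_k_min = heating_rate_k_min)
}

#' Simulate an onset-time table from the Arrhenius nucleation law
#'
#' \eqn{\log_{10} t_{onset}(T) = \log_{10} t_{onset}^0 +
#' (E_{nucl}/(R T))\log_{10}e}, optionally with Gaussian noise in log10
#' space (onset times span decades).
#'
#' @param temperature_k Temperatures (K).
#' @param log10_t_onset0 Intercept, log10 seconds.
#' @param e_nucl_kj_mol Nucleation activation energy (kJ/mol).
#' @param noise_log_sd SD of log10-space noise (decades), >= 0.
#' @param seed Integer seed (required when noisy).
#' @return Tibble: `temperature_k`, `t_onset_s`, `flag` (`"detected"`).
#' @export
#' @examples
#' sim_onset_table(c(361, 363, 366, 368, 373), -19.9, 171)
sim_onset_table <- function(temperature_k, log10_t_onset0, e_nucl_kj_mol,
                            noise_log_sd = 0, seed = NULL) {
  check_scalar(noise_log_sd, "noise_log_sd", lower = 0)
  l10 <- log10_t_onset0 +
    e_nucl_kj_mol * 1000 / (.RGAS * temperature_k) * .LOG10E
  if (noise_log_sd > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_log_sd` > 0.")
    l10 <- withr::with_seed(seed,
                            l10 + rnorm(length(l10), 0, noise_log_sd))
  }
  tibble(temperature_k = temperature_k, t_onset_s = 10^l10,
         flag = "detected")
}
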