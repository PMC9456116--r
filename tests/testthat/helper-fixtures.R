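# Shared fixtures: published parameter sets for the model drug etoricoxib
# (ETB) and the acetylated disaccharide excipient octaacetylmaltose (acMAL),
# used as round-trip ground truths throughout the suite.

vft_etb <- function() vft_params(-16.8, 2730, 265)
vft_etb_20 <- function() vft_params(-19.3, 4000, 244)
vft_etb_30 <- function() vft_params(-17.6, 3200, 254)
vft_etb_40 <- function() vft_params(-16.7, 2880, 258)
vft_etb_50 <- function() vft_params(-16.0, 2635, 261)
vft_acmal <- function() vft_params(-12.3, 1400, 285)

# Arrhenius nucleation law parameters for supercooled ETB and the
# temperatures of its isothermal refractometry runs
nucl_etb <- function() list(log10_t_onset0 = -19.9, e_nucl_kj_mol = 171)
nucl_temps <- c(361, 363, 366, 368, 373)

# calorimetric Tg of the ETB-acMAL series (pure drug ... pure excipient)
tg_table1 <- function() {
  tibble::tibble(
    w_excipient = c(0, 0.1, 0.2, 0.5, 1),
    tg_obs_k = c(330, 329, 327, 326, 332)
  )
}

hn_truth_asym <- function(sigma0 = 1e-10) {
  hn_params(delta_eps = 3, tau_alpha = 1e-3, xi = 0.85, delta = 0.6,
            sigma0 = sigma0, eps_inf = 3)
}

# solve the VFT law numerically for tau(T) = tau_ref: independent oracle for
# the closed-form Tg inversion
root_tg <- function(vft, tau_ref = 100) {
  stats::uniroot(
    function(T_) log10(tau_vft(T_, vft)) - log10(tau_ref),
    lower = vft$T_VFT + 1e-6, upper = vft$T_VFT + 1e4, tol = 1e-10
  )$root
}

# centered numeric derivative of log10 tau wrt Tg/T at T = Tg: oracle for
# the closed-form fragility
numeric_fragility <- function(vft, tg, h = 1e-6) {
  f <- function(x) log10(tau_vft(tg / x, vft)) # x = Tg/T
  (f(1 + h) - f(1 - h)) / (2 * h)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
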