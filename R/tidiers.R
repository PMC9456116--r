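# broom-style methods: tidy() returns one row per parameter with delta-method
# standard errors; glance() returns a one-row model summary.

#' @method tidy hn_fit
#' @export
tidy.hn_fit <- function(x, ...) {
  p <- x$params
  cv <- x$covariance
  se_of <- function(term) {
    if (!term %in% rownames(cv)) return(NA_real_)
    sqrt(max(0, cv[term, term]))
  }
  ln10 <- log(10)
  se_deps <- p$delta_eps * ln10 * se_of("l10_deps")
  se_tau <- p$tau_alpha * ln10 * se_of("l10_tau")
  se_xi <- se_of("xi")
  # delta = q / xi
  se_delta <- NA_real_
  if (all(c("xi", "q") %in% rownames(cv))) {
    g <- c(xi = -(p$xi * p$delta) / p$xi^2, q = 1 / p$xi)
    sub <- cv[c("xi", "q"), c("xi", "q")]
    se_delta <- sqrt(max(0, drop(t(g) %*% sub %*% g)))
  }
  se_sigma <- if ("l10_sigma0" %in% rownames(cv)) {
    p$sigma0 * ln10 * se_of("l10_sigma0")
  } else NA_real_
  se_einf <- if ("eps_inf" %in% rownames(cv)) se_of("eps_inf") else NA_real_
  tibble(
    term = c("sigma0", "eps_inf", "delta_eps", "tau_alpha", "xi", "delta"),
    estimate = c(p$sigma0, p$eps_inf, p$delta_eps, p$tau_alpha, p$xi, p$delta),
    std.error = c(se_sigma, se_einf, se_deps, se_tau, se_xi, se_delta)
  )
}

#' @method glance hn_fit
#' @export
glance.hn_fit <- function(x, ...) {
  tibble(
    converged = x$converged,
    residual_norm = x$residual_norm,
    nobs = nrow(x$data),
    tau_alpha_s = x$params$tau_alpha,
    tau_se_log10 = x$tau_se_log10,
    peak_frequency_hz = hn_peak_frequency(x$params),
    temperature_k = x$temperature_k
  )
}

#' @method tidy vft_params
#' @export
tidy.vft_params <- function(x, ...) {
  se <- if (!is.null(x$covariance)) sqrt(pmax(0, diag(x$covariance))) else
    rep(NA_real_, 3)
  tibble(
    term = c("log10_tau0", "A", "T_VFT"),
    estimate = c(x$log10_tau0, x$A, x$T_VFT),
    std.error = unname(se)
  )
}

#' @method glance vft_fit
#' @export
glance.vft_fit <- function(x, ...) {
  tibble(
    converged = isTRUE(x$converged),
    residual_norm = x$residual_norm %||% NA_real_,
    nobs = if (!is.null(x$data)) nrow(x$data) else NA_integer_
  )
}

#' @method tidy nucleation_fit
#' @export
tidy.nucleation_fit <- function(x, ...) {
  se <- sqrt(pmax(0, diag(x$covariance)))
  tibble(
    term = c("log10_t_onset0", "e_nucl_kj_mol"),
    estimate = c(x$log10_t_onset0, x$e_nucl_kj_mol),
    std.error = unname(se)
  )
}

#' @method glance nucleation_fit
#' @export
glance.nucleation_fit <- function(x, ...) {
  tibble(nobs = x$n_used,
         n_censored = sum(x$data$flag != "detected"))
}

#' @method tidy bilinear_fit
#' @export
tidy.bilinear_fit <- function(x, ...) {
  tibble(
    term = c("tg_k", "slope_glass", "slope_liquid", "ri_at_tg"),
    estimate = c(x$tg_k, x$slope_glass, x$slope_liquid, x$ri_at_tg),
    std.error = c(x$tg_se_k, NA, NA, NA)
  )
}

#' @method glance bilinear_fit
#' @export
glance.bilinear_fit <- function(x, ...) {
  tibble(sse = x$sse, nobs = nrow(x$data))
}

#' @method tidy dsc_tg
#' @export
tidy.dsc_tg <- function(x, ...) {
  tibble(term = c("tg_k", "step_height"),
         estimate = c(x$tg_k, x$step_height),
         std.error = c(NA_real_, NA_real_))
}

#' @method glance dsc_tg
#' @export
glance.dsc_tg <- function(x, ...) {
  tibble(nobs = nrow(x$data), noise = x$noise,
         heating_rate_k_min = x$heating_rate_k_min)
}

#' @method tidy onset_detection
#' @export
tidy.onset_detection <- function(x, ...) {
  tibble(term = "t_onset_s", estimate = x$t_onset_s,
         std.error = NA_real_)
}

#' @method glance onset_detection
#' @export
glance.onset_detection <- function(x, ...) {
  tibble(flag = x$flag, sigma = x$sigma, drop_factor = x$drop_factor,
         temperature_k = x$temperature_k, nobs = nrow(x$trace))
}
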