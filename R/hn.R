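#' Havriliak-Negami relaxation parameters
#'
#' Bundles the parameters of the complex-permittivity model
#' \deqn{\varepsilon^*(f) = -\frac{i\sigma_0}{2\pi f \varepsilon_0}
#'   + \varepsilon_\infty
#'   + \frac{\Delta\varepsilon_\alpha}{[1 + (i 2\pi f \tau_\alpha)^\xi]^\delta}}
#' i.e. an ohmic dc-conductivity term plus one Havriliak-Negami (HN)
#' relaxation process. The Debye relaxation is the special case
#' `xi = delta = 1`.
#'
#' @param delta_eps Relaxation strength \eqn{\Delta\varepsilon_\alpha}
#'   (>= 0; zero gives the degenerate relaxation-free limit).
#' @param tau_alpha Structural relaxation time in seconds (> 0).
#' @param xi Symmetric-broadening exponent, 0 < `xi` <= 1.
#' @param delta Asymmetry exponent; the physical region requires
#'   0 < `xi * delta` <= 1.
#' @param sigma0 dc conductivity in S/m (>= 0). Default 0.
#' @param eps_inf High-frequency limit permittivity (>= 1). Default 1.
#'
#' @return An object of class `hn_params` (a validated named list).
#' @export
#' @examples
#' hn_params(delta_eps = 3, tau_alpha = 1e-3, xi = 0.85, delta = 0.6)
hn_params <- function(delta_eps, tau_alpha, xi, delta, sigma0 = 0, eps_inf = 1) {
  check_scalar(sigma0, "sigma0", lower = 0)
  check_scalar(eps_inf, "eps_inf", lower = 1)
  check_scalar(delta_eps, "delta_eps", lower = 0)
  check_scalar(tau_alpha, "tau_alpha", lower = 0, strict_lower = TRUE)
  check_scalar(xi, "xi", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(delta, "delta", lower = 0, strict_lower = TRUE)
  if (xi * delta > 1 + 1e-12) {
    abort(sprintf("`xi * delta` = %g exceeds 1: outside the physical HN region.",
                  xi * delta))
  }
  structure(
    list(sigma0 = sigma0, eps_inf = eps_inf, delta_eps = delta_eps,
         tau_alpha = tau_alpha, xi = xi, delta = delta),
    class = "hn_params"
  )
}

#' @export
print.hn_params <- function(x, ...) {
  cat("<hn_params>\n")
  cat(sprintf("  delta_eps = %g, tau_alpha = %g s, xi = %g, delta = %g\n",
              x$delta_eps, x$tau_alpha, x$xi, x$delta))
  cat(sprintf("  sigma0 = %g S/m, eps_inf = %g\n", x$sigma0, x$eps_inf))
  invisible(x)
}

#' Evaluate the HN + dc-conductivity permittivity model
#'
#' Computes \eqn{\varepsilon^*(f) = \varepsilon'(f) - i\varepsilon''(f)} for
#' the model described in [hn_params()] and returns the real part and the
#' (positive) loss.
#'
#' @param frequency_hz Vector of positive frequencies (Hz).
#' @param params An [hn_params()] object.
#'
#' @return A tibble with columns `frequency_hz`, `eps_real`, `eps_imag`.
#' @export
#' @examples
#' # Debye limit: peak loss delta_eps / 2 at 2*pi*f*tau = 1
#' p <- hn_params(delta_eps = 1, tau_alpha = 1 / (2 * pi), xi = 1, delta = 1,
#'                eps_inf = 2)
#' hn_loss(1, p)
hn_loss <- function(frequency_hz, params) {
  stopifnot(inherits(params, "hn_params"))
  if (!is.numeric(frequency_hz) || any(!is.finite(frequency_hz)) ||
      any(frequency_hz <= 0)) {
    abort("`frequency_hz` must be positive and finite.")
  }
  omega <- 2 * pi * frequency_hz
  # (i w tau)^xi = (w tau)^xi * exp(i pi xi / 2)
  z <- (omega * params$tau_alpha)^params$xi *
    exp(1i * pi * params$xi / 2)
  hn <- params$delta_eps * exp(-params$delta * log(1 + z))
  eps_real <- params$eps_inf + Re(hn)
  eps_imag <- -Im(hn) + params$sigma0 / (omega * .EPS0)
  tibble(frequency_hz = frequency_hz, eps_real = eps_real, eps_imag = eps_imag)
}

#' Closed-form HN loss-peak frequency
#'
#' Frequency of the loss maximum of a single HN process (no conductivity):
#' \deqn{2\pi f_{max}\tau =
#'  \left[\frac{\sin(\pi\xi/(2(\delta+1)))}{\sin(\pi\xi\delta/(2(\delta+1)))}\right]^{1/\xi}}
#'
#' @param params An [hn_params()] object.
#' @return Peak frequency in Hz.
#' @export
hn_peak_frequency <- function(params) {
  stopifnot(inherits(params, "hn_params"))
  xi <- params$xi; delta <- params$delta
  wt <- (sin(pi * xi / (2 * (delta + 1))) /
           sin(pi * xi * delta / (2 * (delta + 1))))^(1 / xi)
  wt / (2 * pi * params$tau_alpha)
}

# model loss for a fit-space parameter vector
# p: named c(l10_deps, l10_tau, xi, q (= xi*delta), [l10_sigma0])
.hn_fitspace_eps <- function(p, freq, eps_inf) {
  pars <- hn_params(
    delta_eps = 10^p[["l10_deps"]],
    tau_alpha = 10^p[["l10_tau"]],
    xi = p[["xi"]],
    delta = p[["q"]] / p[["xi"]],
    sigma0 = if ("l10_sigma0" %in% names(p)) 10^p[["l10_sigma0"]] else 0,
    eps_inf = eps_inf
  )
  hn_loss(freq, pars)
}

# data-driven starting values; returns list(p, eps_inf, fit_sigma)
.hn_init <- function(freq, loss, eps_real, init) {
  if (!is.null(init)) {
    p <- c(l10_deps = log10(init$delta_eps), l10_tau = log10(init$tau_alpha),
           xi = init$xi, q = init$xi * init$delta)
    fit_sigma <- init$sigma0 > 0
    if (fit_sigma) p[["l10_sigma0"]] <- log10(init$sigma0)
    return(list(p = p, eps_inf = init$eps_inf, fit_sigma = fit_sigma))
  }
  n <- length(freq)
  # smoothed loss maximum for tau init; ignore the conductivity-dominated
  # low-frequency tail by restricting to where the local log-log slope > -0.8
  llf <- log10(freq); lll <- log10(loss)
  k <- min(7L, if (n %% 2L == 0L) n - 1L else n)
  if (k %% 2L == 0L) k <- k - 1L
  sm <- if (k >= 3) stats::runmed(lll, k) else lll
  slope_lo <- if (n >= 5) {
    lo <- llf <= llf[1] + 1
    if (sum(lo) >= 3) coef(lm(lll[lo] ~ llf[lo]))[[2]] else 0
  } else 0
  fit_sigma <- is.finite(slope_lo) && slope_lo < -0.8
  usable <- rep(TRUE, n)
  if (fit_sigma) {
    # drop the descending head before the peak search
    usable <- seq_len(n) >= which.min(sm[seq_len(max(3L, n %/% 2L))])
  }
  ipk <- which(usable)[which.max(sm[usable])]
  if (length(ipk) == 0 || (ipk %in% c(1L, n) && !fit_sigma)) {
    abort("un-initializable spectrum: no interior loss peak found and no `init` supplied.")
  }
  p <- c(
    l10_deps = log10(2 * loss[ipk]),
    l10_tau = log10(1 / (2 * pi * freq[ipk])),
    xi = 0.8, q = 0.8 * 0.8
  )
  if (fit_sigma) {
    p[["l10_sigma0"]] <- log10(loss[1] * 2 * pi * freq[1] * .EPS0)
  }
  eps_inf <- if (!is.null(eps_real)) max(1, min(eps_real)) else 1
  list(p = p, eps_inf = eps_inf, fit_sigma = fit_sigma)
}

#' Fit the HN + conductivity model to a dielectric spectrum
#'
#' Bounded least squares (Levenberg-Marquardt) on the residuals of
#' \eqn{\log_{10}\varepsilon''} over the fit window; log-space residuals give
#' every decade of the loss equal weight. The physical-region bounds
#' 0 < `xi` <= 1 and 0 < `xi * delta` <= 1 are enforced as box constraints by
#' optimizing over `(xi, xi * delta)`. The dc-conductivity exponent is fixed
#' at 1 (pure ohmic); the conductivity amplitude is only fitted when the
#' low-frequency slope of the loss indicates a conductivity tail (or when the
#' supplied `init` has `sigma0 > 0`).
#'
#' `eps_inf` does not enter the loss, so by default it is recovered after the
#' loss fit as the least-squares offset between measured \eqn{\varepsilon'}
#' and the fitted HN real part (exact on single-process data). With
#' `fit_real = TRUE` the real part joins the residual vector and `eps_inf` is
#' a free parameter of the joint fit.
#'
#' @param spectrum Data frame with columns `frequency_hz` (positive,
#'   ascending), `eps_imag` (> 0), and optionally `eps_real` and
#'   `temperature_k`.
#' @param init Optional [hn_params()] starting estimate. Required when no
#'   loss peak is detectable inside the window.
#' @param fit_window Optional `c(fmin, fmax)` in Hz restricting the fit.
#' @param fit_real If `TRUE`, include \eqn{\varepsilon'} residuals (relative
#'   scale) in the objective. Default `FALSE`.
#'
#' @return An object of class `hn_fit` with elements `params`
#'   ([hn_params()]), `covariance` (fit-space covariance, see Details),
#'   `residual_norm`, `converged`, `tau_se_log10` and the data used.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_hn <- function(spectrum, init = NULL, fit_window = NULL, fit_real = FALSE) {
  spectrum <- as_tibble(spectrum)
  req <- c("frequency_hz", "eps_imag")
  missing_cols <- setdiff(req, names(spectrum))
  if (length(missing_cols)) {
    abort(sprintf("`spectrum` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.unsorted(spectrum$frequency_hz, strictly = TRUE)) {
    abort("`frequency_hz` must be strictly ascending.")
  }
  if (any(spectrum$frequency_hz <= 0)) abort("`frequency_hz` must be positive.")
  dat <- spectrum
  if (!is.null(fit_window)) {
    dat <- dplyr::filter(dat, .data$frequency_hz >= fit_window[1],
                         .data$frequency_hz <= fit_window[2])
  }
  dat <- dplyr::filter(dat, .data$eps_imag > 0)
  has_real <- "eps_real" %in% names(dat) && !all(is.na(dat$eps_real))

  freq <- dat$frequency_hz
  loss <- dat$eps_imag
  n_par_max <- 5L + as.integer(fit_real)
  if (nrow(dat) < 8L) abort("fewer than 8 usable points in the fit window.")

  ini <- .hn_init(freq, loss, if (has_real) dat$eps_real else NULL, init)
  p0 <- ini$p
  eps_inf0 <- ini$eps_inf

  lower <- c(l10_deps = -8, l10_tau = -15, xi = 1e-4, q = 1e-4)
  upper <- c(l10_deps = 8, l10_tau = 8, xi = 1, q = 1)
  if (ini$fit_sigma) {
    lower[["l10_sigma0"]] <- -20; upper[["l10_sigma0"]] <- 2
  }
  joint_real <- fit_real && has_real
  if (joint_real) {
    p0[["eps_inf"]] <- eps_inf0
    lower[["eps_inf"]] <- 1; upper[["eps_inf"]] <- 1e4
  }
  p0 <- pmin(pmax(p0[names(lower)], lower), upper)
  real_scale <- if (joint_real) max(abs(dat$eps_real)) else 1

  resid_fn <- function(p) {
    names(p) <- names(lower)
    einf <- if (joint_real) p[["eps_inf"]] else eps_inf0
    mod <- .hn_fitspace_eps(p, freq, einf)
    r <- log10(mod$eps_imag) - log10(loss)
    if (joint_real) r <- c(r, (mod$eps_real - dat$eps_real) / real_scale)
    r
  }

  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 1e-15)
  )
  p <- setNames(fit$par, names(lower))
  at_bound <- any(abs(p - lower) < 1e-10 & names(p) != "xi" & names(p) != "q") ||
    p[["xi"]] < 1e-3 || p[["q"]] < 1e-3
  converged <- fit$info %in% c(1, 2, 3, 4) && !at_bound

  eps_inf_hat <- eps_inf0
  if (!joint_real && has_real) {
    # eps_inf is a pure offset of eps': closed-form least squares
    mod1 <- .hn_fitspace_eps(p, freq, 1)
    eps_inf_hat <- max(1, 1 + mean(dat$eps_real - mod1$eps_real))
  }
  params <- hn_params(
    delta_eps = 10^p[["l10_deps"]],
    tau_alpha = 10^p[["l10_tau"]],
    xi = p[["xi"]],
    delta = p[["q"]] / p[["xi"]],
    sigma0 = if (ini$fit_sigma) 10^p[["l10_sigma0"]] else 0,
    eps_inf = if (joint_real) p[["eps_inf"]] else eps_inf_hat
  )

  # covariance in fit space from the numeric Jacobian at the optimum
  r0 <- resid_fn(p)
  nres <- length(r0); npar <- length(p)
  J <- matrix(0, nres, npar)
  for (j in seq_len(npar)) {
    h <- max(1e-7, 1e-7 * abs(p[[j]]))
    ph <- p; ph[[j]] <- ph[[j]] + h
    J[, j] <- (resid_fn(ph) - r0) / h
  }
  s2 <- sum(r0^2) / max(1, nres - npar)
  jtj <- crossprod(J)
  covar <- tryCatch(s2 * solve(jtj), error = function(e) {
    s2 * MASS_ginv(jtj)
  })
  dimnames(covar) <- list(names(p), names(p))
  covar <- (covar + t(covar)) / 2

  structure(
    list(
      params = params,
      covariance = covar,
      residual_norm = sqrt(sum(r0^2)),
      converged = converged,
      tau_se_log10 = sqrt(max(0, covar["l10_tau", "l10_tau"])),
      temperature_k = if ("temperature_k" %in% names(dat))
        dat$temperature_k[[1]] else NA_real_,
      data = dat,
      fit_sigma = ini$fit_sigma,
      fit_real = joint_real
    ),
    class = "hn_fit"
  )
}

# Moore-Penrose fallback without importing MASS
MASS_ginv <- function(m, tol = 1e-12) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.hn_fit <- function(x, ...) {
  cat("<hn_fit>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  cat(sprintf("  residual norm (log10 loss space): %.3g\n", x$residual_norm))
  cat(sprintf("  se(log10 tau_alpha) = %.3g\n", x$tau_se_log10))
  invisible(x)
}

#' Assemble a relaxation map from per-temperature HN fits
#'
#' Collects the structural relaxation time from each converged fit into the
#' (temperature, tau_alpha) table used for VFT analysis. Non-converged fits
#' are dropped with a warning. Rows are sorted by descending inverse
#' temperature (coldest first).
#'
#' @param fits A list of [fit_hn()] results. Fits lacking a stored
#'   temperature must be supplied via `temperatures`.
#' @param temperatures Optional numeric vector (K) overriding the
#'   temperatures stored in the fits.
#'
#' @return A tibble with columns `temperature_k`, `tau_alpha_s`, `tau_sd_s`
#'   (delta-method SD of tau from the fit covariance).
#' @export
build_relaxation_map <- function(fits, temperatures = NULL) {
  if (length(fits) == 0) abort("no fits supplied.")
  if (inherits(fits, "hn_fit")) fits <- list(fits)
  temps <- temperatures %||% vapply(fits, function(f) f$temperature_k, 0)
  if (anyNA(temps)) abort("every fit needs a temperature (column or argument).")
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!all(conv)) {
    warn(sprintf("dropping %d non-converged fit(s) at T = %s K.",
                 sum(!conv), paste(temps[!conv], collapse = ", ")))
  }
  if (!any(conv)) abort("no converged fits to build a relaxation map from.")
  tibble(
    temperature_k = temps[conv],
    tau_alpha_s = vapply(fits[conv], function(f) f$params$tau_alpha, 0),
    tau_sd_s = vapply(fits[conv], function(f) {
      f$params$tau_alpha * log(10) * f$tau_se_log10
    }, 0)
  ) |>
    dplyr::arrange(dplyr::desc(1 / .data$temperature_k))
}
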