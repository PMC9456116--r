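#' Vogel-Fulcher-Tammann parameters
#'
#' Container for the VFT law \eqn{\tau_\alpha(T) = \tau_0 \exp(A/(T - T_{VFT}))}
#' that parametrizes the super-Arrhenius slowdown of the structural
#' relaxation on approach to the glass transition.
#'
#' @param log10_tau0 \eqn{\log_{10}(\tau_0/\mathrm{s})}.
#' @param A Strength parameter (K), > 0 (0 allowed only as the degenerate
#'   constant-timescale case).
#' @param T_VFT Vogel temperature (K), >= 0.
#' @param covariance Optional 3x3 covariance of
#'   `(log10_tau0, A, T_VFT)`.
#' @return An object of class `vft_params`.
#' @export
#' @examples
#' vft_params(-16.8, 2730, 265) # a typical fragile drug melt
vft_params <- function(log10_tau0, A, T_VFT, covariance = NULL) {
  check_scalar(log10_tau0, "log10_tau0")
  check_scalar(A, "A", lower = 0)
  check_scalar(T_VFT, "T_VFT", lower = 0)
  if (!is.null(covariance)) {
    stopifnot(is.matrix(covariance), all(dim(covariance) == c(3, 3)))
    covariance <- (covariance + t(covariance)) / 2
  }
  structure(list(log10_tau0 = log10_tau0, A = A, T_VFT = T_VFT,
                 covariance = covariance),
            class = "vft_params")
}

#' @export
print.vft_params <- function(x, ...) {
  cat("<vft_params>\n")
  cat(sprintf("  log10(tau0/s) = %.4g, A = %.5g K, T_VFT = %.5g K\n",
              x$log10_tau0, x$A, x$T_VFT))
  if (isFALSE(x$converged)) cat("  (fit NOT converged)\n")
  invisible(x)
}

#' Evaluate the VFT relaxation time
#'
#' @param temperature_k Temperatures (K); all must exceed `T_VFT` (the
#'   timescale diverges at the Vogel temperature).
#' @param vft A [vft_params()] object.
#' @return Relaxation times in seconds.
#' @export
tau_vft <- function(temperature_k, vft) {
  stopifnot(inherits(vft, "vft_params"))
  if (any(temperature_k <= vft$T_VFT)) {
    abort(sprintf(
      "all temperatures must exceed T_VFT = %g K (divergent timescale).",
      vft$T_VFT))
  }
  10^vft$log10_tau0 * exp(vft$A / (temperature_k - vft$T_VFT))
}

#' Fit the VFT equation to a relaxation map
#'
#' Least squares on \eqn{\log_{10}\tau_\alpha} versus temperature.
#' For a fixed Vogel temperature the model is linear in
#' `(log10_tau0, A)`, so the fit profiles \eqn{T_{VFT}} over a grid with
#' exact linear solves and then polishes all three parameters with
#' Levenberg-Marquardt. Residuals are unweighted by default (set
#' `weighted = TRUE` to weight by the per-point `tau_sd_s` converted to
#' log10 space).
#'
#' The fit refuses to claim convergence when the fitted Vogel temperature
#' comes within 1 K of the coldest data point: there the extrapolation that
#' downstream Tg / fragility analyses rely on is not trustworthy.
#'
#' @param map Data frame with columns `temperature_k` and `tau_alpha_s`
#'   (optionally `tau_sd_s`). At least 4 points spanning at least 2 decades
#'   of `tau_alpha_s`.
#' @param init Optional [vft_params()] starting values (skips profiling).
#' @param weighted Use `tau_sd_s` as weights. Default `FALSE`.
#' @return A [vft_params()] object with `covariance` filled in and extra
#'   fields `converged`, `residual_norm`, `data`; class
#'   `c("vft_fit", "vft_params")`.
#' @export
fit_vft <- function(map, init = NULL, weighted = FALSE) {
  map <- as_tibble(map)
  if (!all(c("temperature_k", "tau_alpha_s") %in% names(map))) {
    abort("`map` needs columns `temperature_k` and `tau_alpha_s`.")
  }
  map <- dplyr::arrange(map, .data$temperature_k)
  T_ <- map$temperature_k
  y <- log10(map$tau_alpha_s)
  if (anyDuplicated(T_)) abort("temperatures must be unique.")
  if (length(T_) < 4) abort("need at least 4 relaxation-map points.")
  if (diff(range(y)) < 2) {
    abort("relaxation times must span at least 2 decades for a stable VFT fit.")
  }
  w <- rep(1, length(T_))
  if (weighted && "tau_sd_s" %in% names(map) && all(map$tau_sd_s > 0)) {
    w <- 1 / (map$tau_sd_s / (map$tau_alpha_s * log(10)))^2
  }

  sw <- sqrt(w)
  lin_solve <- function(tv) {
    x <- 1 / (T_ - tv)
    f <- stats::.lm.fit(cbind(sw, sw * x), sw * y)
    c(l0 = f$coefficients[1], a = f$coefficients[2] * log(10),
      rss = sum(f$residuals^2))
  }

  if (is.null(init)) {
    tv_grid <- seq(0, min(T_) - 2, length.out = 600)
    prof <- vapply(tv_grid, lin_solve, c(l0 = 0, a = 0, rss = 0))
    ibest <- which.min(prof["rss", ])
    p0 <- c(l10_tau0 = prof["l0", ibest], A = prof["a", ibest],
            T_VFT = tv_grid[ibest])
  } else {
    p0 <- c(l10_tau0 = init$log10_tau0, A = init$A, T_VFT = init$T_VFT)
  }

  resid_fn <- function(p) {
    tv <- p[[3]]
    if (tv >= min(T_)) return(rep(1e6, length(T_)))
    sqrt(w) * (p[[1]] + p[[2]] * .LOG10E / (T_ - tv) - y)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, lower = c(-30, 0, 0), upper = c(10, 1e5, min(T_) - 1e-6),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 1e-15)
  )
  p <- fit$par
  r0 <- resid_fn(p)
  J <- matrix(0, length(r0), 3)
  for (j in 1:3) {
    h <- max(1e-7, 1e-7 * abs(p[[j]]))
    ph <- p; ph[[j]] <- ph[[j]] + h
    J[, j] <- (resid_fn(ph) - r0) / h
  }
  s2 <- sum(r0^2) / max(1, length(r0) - 3)
  covar <- tryCatch(s2 * solve(crossprod(J)),
                    error = function(e) s2 * MASS_ginv(crossprod(J)))
  dimnames(covar) <- list(c("log10_tau0", "A", "T_VFT"),
                          c("log10_tau0", "A", "T_VFT"))

  too_close <- (min(T_) - p[[3]]) < 1
  out <- vft_params(p[[1]], p[[2]], p[[3]], covariance = covar)
  out$converged <- fit$info %in% c(1, 2, 3, 4) && !too_close
  out$residual_norm <- sqrt(sum(r0^2))
  out$data <- map
  class(out) <- c("vft_fit", "vft_params")
  if (too_close) {
    warn(sprintf(
      "fitted T_VFT = %.2f K is within 1 K of the coldest point (%.2f K); convergence not claimed.",
      p[[3]], min(T_)))
  }
  out
}

#' Dielectric glass-transition temperature at a reference timescale
#'
#' Inverts the VFT law in closed form for the temperature at which
#' \eqn{\tau_\alpha} reaches a reference timescale (100 s by convention):
#' \eqn{T_g = T_{VFT} + A/\ln(\tau_{ref}/\tau_0)}. The standard error, when a
#' parameter covariance is available, follows from the delta method.
#'
#' @param vft A [vft_params()] object.
#' @param tau_ref Reference timescale in seconds (default 100); must exceed
#'   \eqn{\tau_0}.
#' @return A one-row tibble: `tg_k`, `tg_se_k`, `tau_ref_s`.
#' @export
tg_at_timescale <- function(vft, tau_ref = 100) {
  stopifnot(inherits(vft, "vft_params"))
  check_scalar(tau_ref, "tau_ref", lower = 0, strict_lower = TRUE)
  if (vft$A <= 0) abort("A = 0: the timescale never grows; Tg is undefined.")
  dlog <- log(10) * (log10(tau_ref) - vft$log10_tau0)
  if (dlog <= 0) {
    abort("`tau_ref` must exceed tau0: no solution of the VFT law.")
  }
  tg <- vft$T_VFT + vft$A / dlog
  se <- NA_real_
  if (!is.null(vft$covariance)) {
    # gradient wrt (log10_tau0, A, T_VFT)
    g <- c(vft$A * log(10) / dlog^2, 1 / dlog, 1)
    se <- sqrt(max(0, drop(t(g) %*% vft$covariance %*% g)))
  }
  tibble(tg_k = tg, tg_se_k = se, tau_ref_s = tau_ref)
}

#' Isobaric fragility (steepness index)
#'
#' The slope of \eqn{\log_{10}\tau_\alpha} versus \eqn{T_g/T} evaluated at
#' \eqn{T = T_g}. For the VFT law this has the closed form
#' \eqn{m_p = A\,T_g / (\ln 10\,(T_g - T_{VFT})^2)}.
#'
#' @param vft A [vft_params()] object.
#' @param tg Glass-transition temperature (K); defaults to
#'   [tg_at_timescale()] at 100 s. Must exceed `T_VFT`.
#' @return The dimensionless fragility \eqn{m_p}.
#' @export
isobaric_fragility <- function(vft, tg = NULL) {
  stopifnot(inherits(vft, "vft_params"))
  if (is.null(tg)) tg <- tg_at_timescale(vft)$tg_k
  check_scalar(tg, "tg", lower = 0, strict_lower = TRUE)
  if (tg <= vft$T_VFT) abort("`tg` must exceed T_VFT.")
  vft$A * tg / (log(10) * (tg - vft$T_VFT)^2)
}

#' Angell classification of a glass former
#'
#' Maps the isobaric fragility onto the conventional classes with closed
#' boundaries: strong (\eqn{m_p \le 30}), moderately fragile
#' (\eqn{30 < m_p < 100}), fragile (\eqn{m_p \ge 100}).
#'
#' @param m_p Isobaric fragility, > 0. Vectorized.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_fragility(c(30, 98, 110))
classify_fragility <- function(m_p) {
  if (any(!is.finite(m_p)) || any(m_p <= 0)) abort("`m_p` must be positive.")
  dplyr::case_when(
    m_p <= 30 ~ "strong",
    m_p < 100 ~ "moderately fragile",
    TRUE ~ "fragile"
  )
}

#' Apparent (windowed) Arrhenius activation energy of the alpha relaxation
#'
#' Over a narrow temperature window the VFT curve is well approximated by an
#' Arrhenius law; the apparent activation energy is the slope of
#' \eqn{\log_{10}\tau_\alpha} versus \eqn{1/T} times \eqn{R/\log_{10}e}.
#' By default the curve fitted by [fit_vft()] is sampled at `n_points`
#' evenly spaced \eqn{1/T} values inside the window; with `source = "map"`
#' the raw relaxation-map points falling inside the window are used instead.
#'
#' @param x A [vft_params()] object or a relaxation-map data frame
#'   (`temperature_k`, `tau_alpha_s`).
#' @param window `c(T_low, T_high)` in K, `T_low < T_high`; must lie above
#'   `T_VFT` (VFT input) or contain at least 3 map points (map input).
#' @param source `"vft"` (default, requires a `vft_params` input) or
#'   `"map"`.
#' @param n_points Number of sampled \eqn{1/T} values (>= 6) for
#'   `source = "vft"`.
#' @return One-row tibble: `e_alpha_kj_mol`, `e_alpha_se_kj_mol`,
#'   `t_low_k`, `t_high_k`, `n_points`.
#' @export
apparent_activation_energy <- function(x, window, source = NULL, n_points = 9) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be c(T_low, T_high) with T_low < T_high.")
  }
  source <- source %||% if (inherits(x, "vft_params")) "vft" else "map"
  if (source == "vft") {
    stopifnot(inherits(x, "vft_params"))
    if (window[1] <= x$T_VFT) {
      abort("window extends to or below T_VFT: outside the validity range.")
    }
    n_points <- max(6, n_points)
    invT <- seq(1 / window[2], 1 / window[1], length.out = n_points)
    T_ <- 1 / invT
    y <- log10(tau_vft(T_, x))
  } else {
    map <- as_tibble(x)
    map <- dplyr::filter(map, .data$temperature_k >= window[1],
                         .data$temperature_k <= window[2])
    if (nrow(map) < 3) abort("fewer than 3 map points inside the window.")
    T_ <- map$temperature_k
    y <- log10(map$tau_alpha_s)
    invT <- 1 / T_
  }
  f <- lm(y ~ invT)
  slope <- coef(f)[["invT"]]
  se_slope <- suppressWarnings(sqrt(diag(vcov(f)))[["invT"]])
  k <- .RGAS / .LOG10E / 1000 # (log10 s * K) -> kJ/mol
  tibble(
    e_alpha_kj_mol = slope * k,
    e_alpha_se_kj_mol = se_slope * k,
    t_low_k = window[1], t_high_k = window[2],
    n_points = length(y)
  )
}

#' One-row dynamic summary of a fitted relaxation map
#'
#' Convenience wrapper combining [tg_at_timescale()],
#' [isobaric_fragility()], [classify_fragility()] and (optionally)
#' [apparent_activation_energy()].
#'
#' @param vft A [vft_params()] object.
#' @param tau_ref Reference timescale (s) defining the dielectric Tg.
#' @param e_alpha_window Optional `c(T_low, T_high)` window (K) for the
#'   apparent Arrhenius energy.
#' @return One-row tibble: `tg_dielectric_k`, `tg_se_k`, `tau_ref_s`, `m_p`,
#'   `class_label`, and when a window is given `e_alpha_kj_mol` with its
#'   window bounds.
#' @export
fragility_report <- function(vft, tau_ref = 100, e_alpha_window = NULL) {
  tg <- tg_at_timescale(vft, tau_ref)
  m <- isobaric_fragility(vft, tg$tg_k)
  out <- tibble(
    tg_dielectric_k = tg$tg_k, tg_se_k = tg$tg_se_k, tau_ref_s = tau_ref,
    m_p = m, class_label = classify_fragility(m)
  )
  if (!is.null(e_alpha_window)) {
    ea <- apparent_activation_energy(vft, e_alpha_window)
    out <- dplyr::bind_cols(out, ea[, c("e_alpha_kj_mol", "e_alpha_se_kj_mol",
                                        "t_low_k", "t_high_k")])
  }
  out
}
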