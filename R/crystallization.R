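#' Detect the isothermal crystallization onset in a refractometry trace
#'
#' During isothermal annealing of a supercooled liquid the refractive index
#' drifts slowly (densification), reaches a well-distinguished maximum, and
#' then drops sharply as crystallization sets in. The time of that maximum is
#' taken as the crystallization onset time, a practical estimate of the
#' nucleation lag time.
#'
#' The trace is smoothed with a centered rolling median of width
#' `smooth_width`; the noise scale \eqn{\sigma} is estimated as the
#' normalized MAD (1.4826 x MAD) of the first differences over the head of
#' the trace, divided by sqrt(2) (differencing doubles the noise variance
#' while cancelling the slow drift). Crystallization is declared if and only if the
#' smoothed trace later falls more than `drop_factor * sigma` below its
#' running maximum; the onset is the global maximum of the smoothed trace
#' before that drop. Traces that never satisfy the drop criterion (e.g. a
#' stable mixture held for the whole experiment) are censored - a
#' first-class outcome, since a formulation's stability claim is exactly
#' such an observation.
#'
#' @param trace Data frame with columns `time_s` (strictly ascending) and
#'   `refractive_index`; at least 50 points. An optional constant
#'   `temperature_k` column is carried into the result.
#' @param smooth_width Rolling-median width in points (odd; default 11).
#' @param drop_factor Detection threshold in noise SDs (default 10).
#'   Raising it can only turn detections into censorings, never the reverse.
#' @param head_fraction Fraction of the trace used for the noise estimate
#'   (default 0.2).
#' @return An object of class `onset_detection`: a list with `t_onset_s`
#'   (NA when censored), `flag` (`"detected"` or `"censored"`),
#'   `temperature_k`, `sigma`, `drop_factor` and the smoothed trace.
#' @export
detect_onset <- function(trace, smooth_width = 11, drop_factor = 10,
                         head_fraction = 0.2) {
  trace <- as_tibble(trace)
  if (!all(c("time_s", "refractive_index") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `refractive_index`.")
  }
  if (nrow(trace) < 50) abort("trace too short: need at least 50 points.")
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly ascending.")
  }
  k <- as.integer(smooth_width)
  if (k %% 2L == 0L) k <- k + 1L
  ri <- trace$refractive_index
  sm <- if (k >= 3) runmed(ri, k, endrule = "median") else ri

  n_head <- max(10L, floor(head_fraction * length(sm)))
  # level-noise SD from first differences of the raw head: differencing a
  # slow drift leaves (nearly) pure noise with SD sqrt(2) times the level SD
  sigma <- mad(diff(ri[seq_len(n_head)])) / sqrt(2)

  runmax <- cummax(sm)
  deficit <- runmax - sm
  below <- which(deficit > drop_factor * sigma)
  temperature_k <- if ("temperature_k" %in% names(trace)) {
    trace$temperature_k[[1]]
  } else NA_real_

  if (length(below) == 0) {
    res <- list(t_onset_s = NA_real_, flag = "censored")
  } else {
    idrop <- below[[1]]
    ipk <- which.max(sm[seq_len(idrop)])
    res <- list(t_onset_s = trace$time_s[[ipk]], flag = "detected")
  }
  structure(
    c(res, list(temperature_k = temperature_k, sigma = sigma,
                drop_factor = drop_factor,
                trace = dplyr::mutate(trace, ri_smooth = sm))),
    class = "onset_detection"
  )
}

#' @export
print.onset_detection <- function(x, ...) {
  cat("<onset_detection>\n")
  if (x$flag == "detected") {
    cat(sprintf("  onset detected at t = %g s", x$t_onset_s))
    if (!is.na(x$temperature_k)) cat(sprintf(" (T = %g K)", x$temperature_k))
    cat("\n")
  } else {
    cat("  censored: no crystallization drop within the experiment\n")
  }
  cat(sprintf("  noise sigma = %.3g RI units, drop threshold = %g sigma\n",
              x$sigma, x$drop_factor))
  invisible(x)
}

#' Collect onset detections into an onset table
#'
#' @param detections A list of [detect_onset()] results (or a single one).
#' @return Tibble with columns `temperature_k`, `t_onset_s`, `flag`.
#' @export
onset_table <- function(detections) {
  if (inherits(detections, "onset_detection")) detections <- list(detections)
  purrr::map_dfr(detections, function(d) {
    tibble(temperature_k = d$temperature_k, t_onset_s = d$t_onset_s,
           flag = d$flag)
  })
}

#' Fit the Arrhenius nucleation law to an onset table
#'
#' Ordinary least squares of \eqn{\log_{10} t_{onset}} on \eqn{1/T}:
#' \deqn{\log_{10} t_{onset} = \log_{10} t_{onset}^0
#'   + \frac{E_{nucl}}{R\,T}\log_{10}e}
#' The slope converts to the nucleation activation energy via
#' \eqn{E_{nucl} = \mathrm{slope}\cdot R/\log_{10}e}, reported in kJ/mol.
#' Censored rows carry no onset time and are excluded with a warning.
#'
#' @param table Data frame with columns `temperature_k`, `t_onset_s` and
#'   optionally `flag` (`"detected"`/`"censored"`). At least 3 detected rows
#'   at distinct temperatures.
#' @return An object of class `nucleation_fit`: `log10_t_onset0`,
#'   `e_nucl_kj_mol`, `covariance` (2x2, in `(intercept, e_nucl_kj_mol)`
#'   coordinates), `n_used`, `data`.
#' @export
fit_nucleation_arrhenius <- function(table) {
  table <- as_tibble(table)
  if (!all(c("temperature_k", "t_onset_s") %in% names(table))) {
    abort("`table` needs columns `temperature_k` and `t_onset_s`.")
  }
  if (!"flag" %in% names(table)) table$flag <- "detected"
  cen <- table$flag != "detected" | is.na(table$t_onset_s)
  if (any(cen)) {
    warn(sprintf("excluding %d censored/NA row(s) from the nucleation fit.",
                 sum(cen)))
  }
  use <- table[!cen, ]
  if (length(unique(use$temperature_k)) < 3) {
    abort("need at least 3 detected onsets at distinct temperatures.")
  }
  invT <- 1 / use$temperature_k
  y <- log10(use$t_onset_s)
  f <- lm(y ~ invT)
  k <- .RGAS / .LOG10E / 1000 # slope (log10 s * K) -> kJ/mol
  covar <- suppressWarnings(vcov(f))
  scale <- diag(c(1, k))
  covar <- scale %*% covar %*% scale
  dimnames(covar) <- list(c("log10_t_onset0", "e_nucl_kj_mol"),
                          c("log10_t_onset0", "e_nucl_kj_mol"))
  structure(
    list(
      log10_t_onset0 = coef(f)[[1]],
      e_nucl_kj_mol = coef(f)[[2]] * k,
      covariance = covar,
      n_used = nrow(use),
      data = use
    ),
    class = "nucleation_fit"
  )
}

#' @export
print.nucleation_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  cat("<nucleation_fit>\n")
  cat(sprintf("  log10(t_onset0/s) = %.3g +/- %.2g\n",
              x$log10_t_onset0, se[[1]]))
  cat(sprintf("  E_nucl = %.4g +/- %.2g kJ/mol  (n = %d)\n",
              x$e_nucl_kj_mol, se[[2]], x$n_used))
  invisible(x)
}

#' Predict the crystallization onset time at a temperature
#'
#' Forward evaluation of the fitted Arrhenius nucleation law, with an
#' optional delta-method standard error of \eqn{\log_{10} t_{onset}}.
#'
#' @param fit A [fit_nucleation_arrhenius()] result, or any list with
#'   `log10_t_onset0` and `e_nucl_kj_mol` (and optionally `covariance`).
#' @param temperature_k Temperatures (K), > 0.
#' @return Tibble: `temperature_k`, `t_onset_s`, `t_onset_h`,
#'   `log10_t_onset`, `log10_se`.
#' @export
#' @examples
#' fit <- list(log10_t_onset0 = -19.9, e_nucl_kj_mol = 171)
#' predict_onset_time(fit, 368) # about 6.6 h
predict_onset_time <- function(fit, temperature_k) {
  if (any(temperature_k <= 0)) abort("`temperature_k` must be positive.")
  slope_term <- fit$e_nucl_kj_mol * 1000 / (.RGAS * temperature_k) * .LOG10E
  l10 <- fit$log10_t_onset0 + slope_term
  se <- rep(NA_real_, length(temperature_k))
  if (!is.null(fit$covariance)) {
    for (i in seq_along(temperature_k)) {
      g <- c(1, 1000 * .LOG10E / (.RGAS * temperature_k[[i]]))
      se[[i]] <- sqrt(max(0, drop(t(g) %*% fit$covariance %*% g)))
    }
  }
  tibble(
    temperature_k = temperature_k,
    t_onset_s = 10^l10,
    t_onset_h = 10^l10 / 3600,
    log10_t_onset = l10,
    log10_se = se
  )
}

#' Dynamics-crystallization coupling parameter
#'
#' The ratio \eqn{S = E_{nucl}/E_\alpha} between the nucleation activation
#' energy and the apparent activation energy of the structural relaxation,
#' both evaluated over the same temperature window (the ratio is physically
#' meaningful only when the windows match). \eqn{S = 1} means crystallization
#' kinetics fully track the global molecular mobility.
#'
#' @param e_nucl_kj_mol Nucleation activation energy (kJ/mol), > 0.
#' @param e_alpha_kj_mol Structural-relaxation activation energy (kJ/mol),
#'   > 0.
#' @param window `c(T_low, T_high)` (K) shared by both energies.
#' @param window_alpha Optional second window; must equal `window` (supply
#'   it to assert the match explicitly).
#' @param e_nucl_se,e_alpha_se Optional standard errors for uncertainty
#'   propagation.
#' @return One-row tibble: `e_nucl_kj_mol`, `e_alpha_kj_mol`, `s_coupling`,
#'   `s_se`, `t_low_k`, `t_high_k`.
#' @export
#' @examples
#' coupling_parameter(171, 290, window = c(361.15, 373.15)) # S ~ 0.59
coupling_parameter <- function(e_nucl_kj_mol, e_alpha_kj_mol, window,
                               window_alpha = NULL,
                               e_nucl_se = NA_real_, e_alpha_se = NA_real_) {
  check_scalar(e_nucl_kj_mol, "e_nucl_kj_mol", lower = 0, strict_lower = TRUE)
  check_scalar(e_alpha_kj_mol, "e_alpha_kj_mol", lower = 0, strict_lower = TRUE)
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be c(T_low, T_high) with T_low < T_high.")
  }
  if (!is.null(window_alpha) && !isTRUE(all.equal(window, window_alpha))) {
    abort("the two energies were evaluated over different temperature windows; the coupling ratio requires identical windows.")
  }
  s <- e_nucl_kj_mol / e_alpha_kj_mol
  s_se <- if (is.finite(e_nucl_se) || is.finite(e_alpha_se)) {
    rn <- if (is.finite(e_nucl_se)) (e_nucl_se / e_nucl_kj_mol)^2 else 0
    ra <- if (is.finite(e_alpha_se)) (e_alpha_se / e_alpha_kj_mol)^2 else 0
    s * sqrt(rn + ra)
  } else NA_real_
  tibble(
    e_nucl_kj_mol = e_nucl_kj_mol, e_alpha_kj_mol = e_alpha_kj_mol,
    s_coupling = s, s_se = s_se,
    t_low_k = window[1], t_high_k = window[2]
  )
}
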