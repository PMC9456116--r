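# Diagnostic figures. Each fitted object gets an autoplot() method; a couple
# of table-level plot_*() helpers cover the relaxation map and the
# Couchman-Karasz divergence.

#' @method autoplot hn_fit
#' @export
autoplot.hn_fit <- function(object, n_curve = 400, ...) {
  dat <- object$data
  fgrid <- 10^seq(log10(min(dat$frequency_hz)), log10(max(dat$frequency_hz)),
                  length.out = n_curve)
  curve <- hn_loss(fgrid, object$params)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$frequency_hz,
                                    y = .data$eps_imag)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "dielectric loss ε″",
                  title = "Havriliak–Negami fit")
}

#' @method autoplot vft_fit
#' @export
autoplot.vft_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  tgrid <- seq(min(dat$temperature_k), max(dat$temperature_k),
               length.out = n_curve)
  curve <- tibble(temperature_k = tgrid,
                  tau_alpha_s = tau_vft(tgrid, object))
  ggplot2::ggplot(dat, ggplot2::aes(x = 1000 / .data$temperature_k,
                                    y = log10(.data$tau_alpha_s))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "1000 / T (1/K)",
                  y = expression(log[10] * tau[alpha] ~ "(s)"),
                  title = "VFT relaxation map")
}

#' @method autoplot onset_detection
#' @export
autoplot.onset_detection <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$time_s / 3600,
                                    y = .data$refractive_index)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ri_smooth), colour = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "refractive index",
                  title = sprintf("Crystallization onset (%s)", object$flag))
  if (object$flag == "detected") {
    p <- p + ggplot2::geom_vline(xintercept = object$t_onset_s / 3600,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' @method autoplot nucleation_fit
#' @export
autoplot.nucleation_fit <- function(object, ...) {
  dat <- object$data
  pred <- predict_onset_time(object, dat$temperature_k)
  ggplot2::ggplot(dat, ggplot2::aes(x = 1000 / .data$temperature_k,
                                    y = log10(.data$t_onset_s))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = dplyr::mutate(pred,
                                            t_onset_s = .data$t_onset_s),
                       colour = "firebrick") +
    ggplot2::labs(x = "1000 / T (1/K)",
                  y = expression(log[10] * t[onset] ~ "(s)"),
                  title = "Arrhenius nucleation law")
}

#' @method autoplot bilinear_fit
#' @export
autoplot.bilinear_fit <- function(object, ...) {
  dat <- object$data
  rng_lo <- range(dat$temperature_k[dat$temperature_k <= object$tg_k])
  rng_hi <- range(dat$temperature_k[dat$temperature_k >= object$tg_k])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$temperature_k,
                                    y = .data$refractive_index)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$ri_at_tg -
                           object$slope_glass * object$tg_k,
                         slope = object$slope_glass, colour = "steelblue") +
    ggplot2::geom_abline(intercept = object$ri_at_tg -
                           object$slope_liquid * object$tg_k,
                         slope = object$slope_liquid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$tg_k, linetype = 2) +
    ggplot2::labs(x = "temperature (K)", y = "refractive index",
                  title = sprintf("Bilinear Tg = %.1f K", object$tg_k))
}

#' @method autoplot dsc_tg
#' @export
autoplot.dsc_tg <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$temperature_k,
                                    y = .data$heat_flow)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(intercept = object$baseline_low[[1]],
                         slope = object$baseline_low[[2]],
                         linetype = 3) +
    ggplot2::geom_abline(intercept = object$baseline_high[[1]],
                         slope = object$baseline_high[[2]],
                         linetype = 3) +
    ggplot2::geom_vline(xintercept = object$tg_k, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "temperature (K)", y = "heat flow (W/g)",
                  title = sprintf("DSC midpoint Tg = %.1f K", object$tg_k))
}

#' Plot a relaxation map
#'
#' @param map Tibble with `temperature_k`, `tau_alpha_s`.
#' @return A ggplot.
#' @export
plot_relaxation_map <- function(map) {
  ggplot2::ggplot(as_tibble(map),
                  ggplot2::aes(x = 1000 / .data$temperature_k,
                               y = log10(.data$tau_alpha_s))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "1000 / T (1/K)",
                  y = expression(log[10] * tau[alpha] ~ "(s)"))
}

#' Plot observed mixture Tg against the Couchman-Karasz prediction
#'
#' @param divergence Output of [ck_divergence()].
#' @return A ggplot.
#' @export
plot_ck_divergence <- function(divergence) {
  ggplot2::ggplot(divergence, ggplot2::aes(x = .data$w_excipient)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$tg_ck_k),
                       colour = "grey40", linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$tg_obs_k,
                                     colour = .data$minimum_flag),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "excipient mass fraction", y = "Tg (K)",
                  title = "Couchman–Karasz prediction vs observation")
}
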