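#' Heat-capacity-jump ratio K for the Couchman-Karasz equation
#'
#' \eqn{K = \Delta C_p^{excipient}/\Delta C_p^{drug}}, the ratio of the
#' heat-capacity jumps at Tg of the two pure components; a measure of the
#' component interactions entering the mixture-Tg prediction.
#'
#' @param dcp_excipient,dcp_drug Heat-capacity jumps at Tg, J/(g K), > 0.
#' @return The dimensionless ratio K.
#' @export
#' @examples
#' k_from_delta_cp(0.350, 0.347) # 1.009
k_from_delta_cp <- function(dcp_excipient, dcp_drug) {
  check_scalar(dcp_excipient, "dcp_excipient", lower = 0, strict_lower = TRUE)
  check_scalar(dcp_drug, "dcp_drug", lower = 0, strict_lower = TRUE)
  dcp_excipient / dcp_drug
}

#' Couchman-Karasz mixture glass-transition temperature
#'
#' Predicts the Tg of a binary amorphous mixture from the component Tg
#' values, the mass fractions, and the heat-capacity-jump ratio K:
#' \deqn{T_g = \frac{w_{drug} T_g^{drug} + K\, w_{exc} T_g^{exc}}
#'   {w_{drug} + K\, w_{exc}}}
#' With K = 1 this reduces exactly to the linear mass-weighted mixing rule.
#'
#' @param w_excipient Mass fraction of the excipient, in `[0, 1]`
#'   (vectorized); `w_drug = 1 - w_excipient`.
#' @param tg_drug,tg_excipient Component glass-transition temperatures (K).
#' @param k Heat-capacity-jump ratio from [k_from_delta_cp()], > 0.
#' @return Predicted mixture Tg (K), same length as `w_excipient`.
#' @export
#' @examples
#' couchman_karasz_tg(0.5, tg_drug = 330, tg_excipient = 332, k = 1.009)
couchman_karasz_tg <- function(w_excipient, tg_drug, tg_excipient, k) {
  if (any(w_excipient < 0 | w_excipient > 1)) {
    abort("`w_excipient` must lie in [0, 1].")
  }
  check_scalar(tg_drug, "tg_drug", lower = 0, strict_lower = TRUE)
  check_scalar(tg_excipient, "tg_excipient", lower = 0, strict_lower = TRUE)
  check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  w_drug <- 1 - w_excipient
  (w_drug * tg_drug + k * w_excipient * tg_excipient) /
    (w_drug + k * w_excipient)
}

#' Divergence of observed mixture Tg from the Couchman-Karasz prediction
#'
#' Evaluates the Couchman-Karasz prediction at each observed composition and
#' reports `tg_obs_k - tg_ck_k`. An interior composition whose observed Tg
#' sits below both neighbors is flagged (`minimum_flag`): such a Tg minimum
#' cannot be produced by the monotone Couchman-Karasz curve and signals
#' specific drug-excipient interactions.
#'
#' @param observed Data frame with columns `w_excipient` (in `[0, 1]`) and
#'   `tg_obs_k` (K).
#' @param tg_drug,tg_excipient,k As in [couchman_karasz_tg()].
#' @return Tibble: `w_excipient`, `tg_obs_k`, `tg_ck_k`, `divergence_k`,
#'   `minimum_flag`.
#' @export
ck_divergence <- function(observed, tg_drug, tg_excipient, k) {
  observed <- as_tibble(observed)
  if (!all(c("w_excipient", "tg_obs_k") %in% names(observed))) {
    abort("`observed` needs columns `w_excipient` and `tg_obs_k`.")
  }
  observed <- dplyr::arrange(observed, .data$w_excipient)
  pred <- couchman_karasz_tg(observed$w_excipient, tg_drug, tg_excipient, k)
  n <- nrow(observed)
  minflag <- rep(FALSE, n)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      minflag[i] <- observed$tg_obs_k[i] < observed$tg_obs_k[i - 1] &&
        observed$tg_obs_k[i] < observed$tg_obs_k[i + 1]
    }
  }
  dplyr::mutate(observed, tg_ck_k = pred,
                divergence_k = .data$tg_obs_k - pred,
                minimum_flag = minflag)
}

#' Glass-transition temperature from a bilinear refractive-index scan
#'
#' On cooling through the glass transition the refractive index follows two
#' nearly linear branches (liquid and glass) with different slopes; Tg is
#' the temperature at their intersection. The breakpoint is found by
#' scanning candidate temperatures over the interior of the scan, fitting a
#' line to the points on each side while excluding a
#' `+/- exclusion_halfwidth` band around the candidate (the transition
#' region is curved in real data), and minimizing the total residual sum of
#' squares; the reported Tg is the intersection of the two winning lines.
#'
#' When the two slopes are statistically indistinguishable (their difference
#' is within the joint 95% band) there is no detectable transition and an
#' error of class `amglass_no_transition` is raised.
#'
#' @param trace Data frame with columns `temperature_k` and
#'   `refractive_index` (any monotone temperature ordering).
#' @param exclusion_halfwidth Half-width (K) of the band excluded around the
#'   candidate breakpoint (default 2).
#' @param min_side_points Minimum points required on each side (default 10).
#' @return Object of class `bilinear_fit`: `tg_k`, `tg_se_k`,
#'   `slope_liquid`, `slope_glass`, `ri_at_tg`, `sse`, plus the data.
#' @export
tg_from_bilinear <- function(trace, exclusion_halfwidth = 2,
                             min_side_points = 10) {
  trace <- as_tibble(trace)
  if (!all(c("temperature_k", "refractive_index") %in% names(trace))) {
    abort("`trace` needs columns `temperature_k` and `refractive_index`.")
  }
  trace <- dplyr::arrange(trace, .data$temperature_k)
  T_ <- trace$temperature_k
  ri <- trace$refractive_index
  n <- length(T_)
  if (n < 2 * min_side_points + 1) abort("trace too short for breakpoint search.")

  cand <- T_[T_ > T_[min_side_points] & T_ < T_[n - min_side_points + 1]]
  if (length(cand) == 0) abort("no admissible breakpoint candidates.")

  best <- NULL
  for (tc in cand) {
    lo <- T_ < tc - exclusion_halfwidth
    hi <- T_ > tc + exclusion_halfwidth
    if (sum(lo) < min_side_points || sum(hi) < min_side_points) next
    flo <- stats::.lm.fit(cbind(1, T_[lo]), ri[lo])
    fhi <- stats::.lm.fit(cbind(1, T_[hi]), ri[hi])
    sse <- sum(flo$residuals^2) + sum(fhi$residuals^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(tc = tc, sse = sse, lo = lo, hi = hi)
    }
  }
  if (is.null(best)) abort("breakpoint search failed: sides too thin everywhere.")

  dlo <- data.frame(T = T_[best$lo], ri = ri[best$lo])
  dhi <- data.frame(T = T_[best$hi], ri = ri[best$hi])
  flo <- lm(ri ~ T, data = dlo)
  fhi <- lm(ri ~ T, data = dhi)
  b_lo <- coef(flo); b_hi <- coef(fhi)
  se_lo <- suppressWarnings(sqrt(diag(vcov(flo)))[["T"]])
  se_hi <- suppressWarnings(sqrt(diag(vcov(fhi)))[["T"]])
  dslope <- b_hi[["T"]] - b_lo[["T"]]
  se_d <- sqrt(se_lo^2 + se_hi^2)
  if ((is.finite(se_d) && abs(dslope) <= qnorm(0.975) * se_d) ||
      abs(dslope) < 1e-12 * max(abs(b_lo[["T"]]), abs(b_hi[["T"]]), 1e-300)) {
    abort("no transition detected: glass and liquid slopes are statistically indistinguishable.",
          class = "amglass_no_transition")
  }
  tg <- -(b_hi[[1]] - b_lo[[1]]) / dslope
  # delta-method SE of the intersection from the two independent line fits
  g_lo <- c(1 / dslope, tg / dslope)
  g_hi <- -g_lo
  var_tg <- suppressWarnings(drop(t(g_lo) %*% vcov(flo) %*% g_lo +
                                    t(g_hi) %*% vcov(fhi) %*% g_hi))
  structure(
    list(
      tg_k = tg,
      tg_se_k = sqrt(max(0, var_tg)),
      slope_glass = b_lo[["T"]], slope_liquid = b_hi[["T"]],
      ri_at_tg = b_lo[[1]] + b_lo[["T"]] * tg,
      sse = best$sse,
      exclusion_halfwidth = exclusion_halfwidth,
      data = trace
    ),
    class = "bilinear_fit"
  )
}

#' @export
print.bilinear_fit <- function(x, ...) {
  cat("<bilinear_fit>\n")
  cat(sprintf("  Tg = %.2f +/- %.2g K (slope intersection)\n",
              x$tg_k, x$tg_se_k))
  cat(sprintf("  slopes: glass %.3g, liquid %.3g RI/K\n",
              x$slope_glass, x$slope_liquid))
  invisible(x)
}

#' Glass-transition temperature from a DSC heat-flow step
#'
#' The glass transition appears as a sigmoidal jump in the normalized heat
#' flow on heating. Linear baselines are fitted over the outer portions of
#' the scan (below and above the step), and Tg is the temperature at which
#' the signal crosses the half-height between the extrapolated baselines -
#' the conventional midpoint construction.
#'
#' @param trace Data frame with columns `temperature_k` (ascending) and
#'   `heat_flow` (normalized, W/g); optional `heating_rate_k_min` metadata
#'   column is carried through.
#' @param baseline_fraction Fraction of the scan at each end used for the
#'   baseline fits (default 1/3).
#' @param min_step Minimum step height (W/g) regarded as a real transition;
#'   below it an error of class `amglass_no_transition` is raised. Default
#'   `1e-6` plus 3x the baseline residual noise.
#' @return Object of class `dsc_tg`: `tg_k`, `step_height`, baselines,
#'   data.
#' @export
tg_from_dsc_step <- function(trace, baseline_fraction = 1 / 3,
                             min_step = NULL) {
  trace <- as_tibble(trace)
  if (!all(c("temperature_k", "heat_flow") %in% names(trace))) {
    abort("`trace` needs columns `temperature_k` and `heat_flow`.")
  }
  if (is.unsorted(trace$temperature_k, strictly = TRUE)) {
    abort("`temperature_k` must be strictly ascending.")
  }
  T_ <- trace$temperature_k
  hf <- trace$heat_flow
  n <- length(T_)
  if (n < 20) abort("trace too short for baseline construction.")
  nb <- max(5L, floor(baseline_fraction * n))
  lo <- seq_len(nb); hi <- seq(n - nb + 1L, n)
  flo <- lm(hf[lo] ~ T_[lo]); fhi <- lm(hf[hi] ~ T_[hi])
  base_lo <- coef(flo)[[1]] + coef(flo)[[2]] * T_
  base_hi <- coef(fhi)[[1]] + coef(fhi)[[2]] * T_
  noise <- stats::sd(c(flo$residuals, fhi$residuals))
  step_mid <- base_hi - base_lo
  if (is.null(min_step)) min_step <- 1e-6 + 3 * noise
  # half-height crossing: signal relative to the baseline midline
  rel <- hf - (base_lo + base_hi) / 2
  interior <- seq(max(lo) + 1L, min(hi) - 1L)
  sgn <- sign(rel)
  cross <- which(sgn[-1] != sgn[-n] & seq_len(n - 1) %in% interior)
  if (length(cross) == 0 || mean(abs(step_mid[interior])) < min_step) {
    abort("no detectable heat-flow step in the scan.",
          class = "amglass_no_transition")
  }
  i <- cross[[1]]
  # linear interpolation of the zero crossing of `rel`
  tg <- T_[i] - rel[i] * (T_[i + 1] - T_[i]) / (rel[i + 1] - rel[i])
  step_height <- (coef(fhi)[[1]] + coef(fhi)[[2]] * tg) -
    (coef(flo)[[1]] + coef(flo)[[2]] * tg)
  if (abs(step_height) < min_step) {
    abort("no detectable heat-flow step in the scan.",
          class = "amglass_no_transition")
  }
  structure(
    list(
      tg_k = tg, step_height = step_height,
      baseline_low = coef(flo), baseline_high = coef(fhi),
      noise = noise,
      heating_rate_k_min = if ("heating_rate_k_min" %in% names(trace)) {
        trace$heating_rate_k_min[[1]]
      } else NA_real_,
      data = trace
    ),
    class = "dsc_tg"
  )
}

#' @export
print.dsc_tg <- function(x, ...) {
  cat("<dsc_tg>\n")
  cat(sprintf("  Tg (midpoint) = %.2f K, step height = %.3g W/g\n",
              x$tg_k, x$step_height))
  invisible(x)
}
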