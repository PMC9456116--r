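---
title: "Methods: glass-transition dynamics and physical stability of amorphous drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glass-transition dynamics and physical stability of amorphous drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amglass)
```

## Scope and scientific background

Amorphous (glassy) forms of poorly soluble drugs dissolve faster than their
crystals but are thermodynamically unstable: held above or even below the
glass transition they eventually recrystallize and lose the solubility
advantage. Assessing a formulation therefore hinges on three linked
characterizations that this package implements end to end:

1. **Molecular dynamics** — broadband dielectric spectroscopy (BDS) yields
   the structural (α) relaxation time τ~α~(T); its temperature dependence
   gives a dielectric glass-transition temperature T~g~ and the isobaric
   fragility m~p~.
2. **Crystallization kinetics** — isothermal refractometry detects the
   onset of crystallization; onset times versus temperature give a
   nucleation activation energy E~nucl~, and its ratio to the dynamic
   activation energy E~α~ quantifies how strongly crystallization tracks
   molecular mobility.
3. **Mixture thermodynamics** — the Couchman–Karasz equation predicts the
   T~g~ of a binary drug–excipient mixture from component data; systematic
   divergence of observed T~g~ from that prediction (in particular a T~g~
   minimum at intermediate composition) is a signature of specific
   drug–excipient interactions.

Because no public instrument data accompany this problem class, the package
ships a synthetic-data generator that emulates each instrument modality with
known ground truth; every estimator is validated by round trips against it.

## Dielectric model

A measured spectrum at one temperature is the complex permittivity
ε\*(f) = ε′(f) − iε″(f) on a frequency grid (typically 10^−2^–10^6^ Hz). It
is modelled as one Havriliak–Negami (HN) process plus an ohmic
dc-conductivity term:

$$\varepsilon^*(f) = -\frac{i\sigma_0}{2\pi f\varepsilon_0}
 + \varepsilon_\infty
 + \frac{\Delta\varepsilon_\alpha}{\left[1 + (i2\pi f\tau_\alpha)^{\xi}\right]^{\delta}}$$

with relaxation strength Δε~α~ > 0, relaxation time τ~α~ > 0, symmetric
broadening ξ ∈ (0, 1], asymmetry δ > 0 with ξδ ≤ 1, dc conductivity σ~0~ ≥ 0
(S/m) and high-frequency limit ε~∞~ ≥ 1. The Debye case is ξ = δ = 1. The
loss peak sits at the closed-form frequency
2πf~max~τ = [sin(πξ/(2(δ+1)))/sin(πξδ/(2(δ+1)))]^1/ξ^, which the tests use
as an independent oracle.

### Fitting choices

* **Objective.** `fit_hn()` minimizes residuals of log~10~ε″ over the fit
  window (bounded Levenberg–Marquardt). The loss spans several decades, so
  log-space residuals weight every decade equally; fitting ε′ as well is
  available via `fit_real = TRUE` but is not the default.
* **Bounds.** The optimizer works in (ξ, ξδ) ∈ (0, 1]², which makes the
  physical HN region a box constraint. δ itself is deliberately *not*
  bounded above by 1 — only ξδ ≤ 1 is enforced; this is the wider of the
  two conventional choices and the fit reports whichever δ the data
  support.
* **Conductivity.** The conductivity exponent is fixed at 1 (pure ohmic).
  σ~0~ enters the fit (as log~10~σ~0~) only when the low-frequency slope of
  the loss approaches −1, the signature of a dc tail; otherwise it is
  pinned at zero. This keeps the parameter count minimal on
  conductivity-free spectra.
* **ε~∞~.** The loss does not constrain ε~∞~. When ε′ data are present it
  is recovered after the loss fit as the closed-form least-squares offset
  between measured ε′ and the fitted HN real part — exact on
  single-process data; otherwise it defaults to the minimum of ε′ (or 1).
* **Initialization.** τ from the smoothed loss maximum
  (τ = 1/2πf~peak~), Δε = 2ε″~max~, ξ = δ = 0.8, σ~0~ from the
  lowest-decade amplitude when the tail is present. A spectrum with no
  interior peak and no user-supplied initial estimate is rejected rather
  than silently mis-fit.
* **Convergence.** A fit that stops on an optimizer failure or lands on a
  parameter bound is flagged `converged = FALSE` and excluded from the
  relaxation map (with a warning) by `build_relaxation_map()`.

One HN process only: secondary (β/γ) relaxations, electrode polarization
and Kramers–Kronig consistency checks are out of scope.

## Relaxation map, T~g~, fragility, windowed activation energy

`fit_vft()` parametrizes the map with the Vogel–Fulcher–Tammann law
τ~α~(T) = τ~0~ exp(A/(T − T~VFT~)), fitted in log~10~τ space. For fixed
T~VFT~ the model is linear in (log~10~τ~0~, A), so the fit profiles T~VFT~
on a grid with exact linear solves before a Levenberg–Marquardt polish —
this makes the noiseless round trips in the test suite exact to machine
precision without a user-supplied start. Residuals are unweighted by
default (a σ-weighted mode exists). The fit requires ≥ 4 points spanning
≥ 2 decades, and it refuses to claim convergence when the fitted T~VFT~
comes within 1 K of the coldest datum, where the downstream extrapolation
is untrustworthy.

* **Dielectric T~g~** (`tg_at_timescale()`): the closed-form inversion
  T~g~ = T~VFT~ + A/ln(τ~ref~/τ~0~) at the conventional reference
  timescale τ~ref~ = 100 s (configurable). Uncertainty by the delta method
  from the fit covariance.
* **Isobaric fragility** (`isobaric_fragility()`):
  m~p~ = A·T~g~/(ln10·(T~g~ − T~VFT~)²), the steepness of log~10~τ~α~
  versus T~g~/T at T~g~. The tests require agreement with a centered
  numeric derivative to 10^−6^ relative. Classification uses the closed
  boundaries strong (m~p~ ≤ 30), moderately fragile (30 < m~p~ < 100),
  fragile (m~p~ ≥ 100).
* **Windowed Arrhenius energy** (`apparent_activation_energy()`): over a
  narrow window the VFT curve is locally Arrhenius;
  E~α~ = slope·R/log~10~e from an OLS fit of log~10~τ~α~ versus 1/T. By
  default the fitted VFT curve is sampled at ≥ 6 evenly spaced 1/T values
  inside the window — experimental maps typically contain few points in
  the crystallization window — with a raw-point mode (`source = "map"`)
  available. VFT convexity guarantees the windowed energy is bracketed by
  the edge-implied local energies, which the suite asserts.

## Crystallization onset and nucleation energetics

During an isothermal hold the refractive index drifts slowly upward
(densification), passes a well-distinguished maximum and then drops
sharply as crystallites scatter and transform the melt. `detect_onset()`
implements exactly this definition: the onset is the time of the global
maximum of the (rolling-median) smoothed trace before the drop.

Turning that graphical definition into an algorithm requires a noise rule;
the package's choices are:

* smoothing: centered rolling median, width 11 points (robust to single
  outliers, preserves the peak location);
* noise scale σ: normalized MAD (1.4826×MAD) of the first differences of
  the *raw* head of the trace, divided by √2 — differencing cancels the
  slow drift and leaves pure noise at √2 times the level SD. (Differencing
  the *smoothed* trace instead would underestimate σ by an order of
  magnitude, because adjacent rolling medians share most of their window,
  and the drop criterion would fire on noise.)
* drop criterion: crystallization is declared iff the smoothed trace falls
  more than `drop_factor` (default 10) × σ below its running maximum.
  Raising the factor can only move runs from detected to censored, never
  the reverse.

Runs that never satisfy the criterion are **censored** — a first-class
outcome, because "the mixture did not crystallize in 22 h" is precisely
the stability claim for a formulation.

Detected onsets at several temperatures feed
`fit_nucleation_arrhenius()`: ordinary least squares of log~10~t~onset~ on
1/T, the slope converting to E~nucl~ = slope·R/log~10~e (kJ/mol
externally, J/mol internally, R = 8.314 J/(mol·K)). Censored rows are
excluded with a warning; at least three detected temperatures are
required. `predict_onset_time()` evaluates the law forward with a
delta-method interval, and `coupling_parameter()` forms
S = E~nucl~/E~α~ — the two energies must share the same temperature
window, which the function enforces. S = 1 would mean crystallization
fully controlled by structural relaxation; values near 0.6 indicate only
partial kinetic control.

## Mixture T~g~: Couchman–Karasz prediction and divergence

With component glass-transition temperatures and heat-capacity jumps, the
mixture T~g~ is predicted as

$$T_g = \frac{w_{drug}T_g^{drug} + K\,w_{exc}T_g^{exc}}
{w_{drug} + K\,w_{exc}}, \qquad K = \frac{\Delta C_p^{exc}}{\Delta C_p^{drug}}$$

with mass fractions throughout. K = 1 reduces exactly to linear mixing;
K > 0 with distinct component T~g~ values makes the curve strictly
monotone in composition. `ck_divergence()` subtracts the prediction from
observed values and flags any interior composition lying below both
neighbours — a T~g~ minimum that no monotone Couchman–Karasz curve can
produce, hence direct evidence for specific interactions.

Two scan-based T~g~ estimators complete the module:

* `tg_from_bilinear()` — refractometric T~g~: RI(T) is bilinear with a
  slope break at T~g~. The breakpoint is found by scanning candidate
  temperatures over the scan interior, fitting a line to each side while
  excluding ±2 K around the candidate (the transition region is curved in
  real data), minimizing total SSE, and intersecting the two winning
  lines. When the side slopes are statistically indistinguishable at 95%
  the function raises a `"no transition"` error instead of reporting a
  meaningless intersection.
* `tg_from_dsc_step()` — calorimetric T~g~: linear baselines are fitted
  over the outer thirds of the scan and T~g~ is where the signal crosses
  the half-height between the extrapolated baselines (the conventional
  midpoint construction). A scan without a resolvable step errors.

## The synthetic-data generator

Every instrument modality has a generator with explicit ground truth and
an explicit seed; no hidden global RNG state is used (generators restore
`.Random.seed`). Noise models match each observable's dynamic range:
multiplicative lognormal on the dielectric loss (it spans decades),
additive Gaussian on refractive index and heat flow, Gaussian in log~10~
space for onset times.

The crystallization trace uses a linear pre-onset drift followed by an
Avrami-type decay ΔRI·(1 − exp(−k(t−t~onset~)^n^)) — the standard
isothermal-transformation form, which guarantees the
maximum-preceding-the-drop morphology by construction. Published traces of
this kind are shown but not parameterized, so the defaults here are the
package's own choices of realistic study conditions: a 22 h experiment
sampled every 10 s, onset near 6 h, RI ≈ 1.53, drift 10^−7^ RI/s, drop
amplitude 0.01, Avrami exponent 2, and additive noise of 5×10^−5^ RI —
half the 10^−4^ resolution of a typical laboratory refractometer. The
cooling-scan generator uses liquid/glass slopes of −4×10^−4^ and
−1.5×10^−4^ RI/K (typical refractometric values for an organic melt) and
the DSC generator a logistic step of 0.06 W/g, the heat flow corresponding
to a ΔC~p~ ≈ 0.35 J/(g·K) jump scanned at 10 K/min.

**What passing tests do and do not show.** The generators produce clean
single-process spectra, strictly bilinear scans, symmetric steps and
white noise. Real data add secondary relaxations, electrode polarization,
curved transition regions, enthalpy-relaxation overshoots and drifts that
are not white; recovery tolerances measured on synthetic data are
therefore best-case figures, not instrument validations.

## Numerical choices and degenerate inputs

* Physical constants are fixed package-wide
  (ε~0~ = 8.8541878128×10^−12^ F/m, R = 8.314 J/(mol·K), log~10~e).
* Temperatures are kelvin everywhere inside the package;
  `celsius_to_kelvin()` converts at the boundary.
* All nonlinear fits run Levenberg–Marquardt to tight tolerances
  (f/p/g-tol 10^−15^) so that noiseless round trips are exact to ≈ 10^−9^
  or better; covariances come from the numeric Jacobian at the optimum.
* Degenerate inputs fail loudly: A = 0 makes T~g~ undefined; τ~ref~ ≤ τ~0~
  has no VFT solution; equal bilinear slopes or a zero DSC step raise
  `"no transition"`; onset tables with < 3 detected temperatures refuse to
  fit; spectra with no interior loss peak and no initial estimate are
  rejected as un-initializable.
* Problem sizes in the test suite are the package's own choices: 12–15
  temperature points per VFT series, 105-point spectra (13
  points/decade over 8 decades), 100-seed Monte-Carlo recovery studies for
  the scan estimators and onset detection, 50 seeds for noisy HN fits and
  200 for noisy VFT fits.

## Worked example

```{r example}
# molecular dynamics of the pure supercooled drug
vft <- fit_vft(sim_relaxation_series(vft_params(-16.8, 2730, 265),
                                     seq(330, 380, length.out = 12)))
fragility_report(vft, e_alpha_window = c(361.15, 373.15))

# crystallization energetics from a noiseless onset table
nucl <- fit_nucleation_arrhenius(
  sim_onset_table(c(361, 363, 366, 368, 373), -19.9, 171))
tidy(nucl)
predict_onset_time(nucl, 368)

# mixture thermodynamics
k <- k_from_delta_cp(0.350, 0.347)
ck_divergence(
  data.frame(w_excipient = c(0, 0.1, 0.2, 0.5, 1),
             tg_obs_k = c(330, 329, 327, 326, 332)),
  tg_drug = 330, tg_excipient = 332, k = k)
```

## Known limitations

* One relaxation process per spectrum; spectra with resolved β-wings will
  bias ξ and δ.
* The dc-conductivity exponent is fixed at 1; fractional-power
  conductivity (electrode effects) is not modelled.
* `apparent_activation_energy()` assumes the window lies inside the VFT
  validity range; it does not extrapolate below T~VFT~.
* The Couchman–Karasz module covers binary mixtures only, with
  mass-fraction weighting; no Gordon–Taylor density-based K, no ternary
  systems, no enthalpy-relaxation (aging) analysis.
* Onset analysis stops at the onset: overall-crystallization (Avrami)
  kinetics, crystal-growth modelling and classical-nucleation-theory
  decompositions are out of scope.
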