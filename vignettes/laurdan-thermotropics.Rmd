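---
title: "Laurdan GP thermotropics: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laurdan GP thermotropics: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laurdanGP)
```

## The measurement and the model

Laurdan is a lipophilic solvatochromatic dye: its emission maximum sits
near 440 nm in a tightly packed (gel) bilayer and red-shifts towards
490 nm as water penetrates a loosely packed (liquid-crystalline)
bilayer. The generalized polarization

$$\mathrm{GP} = \frac{I_{440} - I_{490}}{I_{440} + I_{490}}$$

maps each emission spectrum onto $[-1, 1]$, higher meaning tighter
packing. Scanning temperature produces a sigmoidal GP curve across the
melting transition.

The package models that curve as a **two-state system**. The gel-phase
occupancy is logistic,

$$f(T) = \frac{1}{1 + e^{(T - T_M)/k}},$$

and the observed GP is the occupancy-weighted mixture of two plateau
lines:

$$\mathrm{GP}(T) = \bigl[g_{gel} + s_{gel}(T - T_M)\bigr] f(T) +
  \bigl[g_{fluid} + s_{fluid}(T - T_M)\bigr]\,(1 - f(T)),$$

clamped to $[-1, 1]$. Parameters (all set per condition in
`lipid_conditions()`, constructed with `melt_model()`):

| parameter | meaning | units | default source |
|---|---|---|---|
| `t_m` | transition temperature | °C | literature values (LUVs); printed nanodisc shifts |
| `width_k` | transition width; FWHM of the $-d\mathrm{GP}/dT$ peak is $2\ln(3+2\sqrt2)\,k \approx 3.5255\,k$ | °C | chosen (see below) |
| `gp_gel`, `gp_fluid` | plateau GP levels | — | chosen to match typical Laurdan contrast |
| `slope_gel`, `slope_fluid` | linear plateau drifts | GP/°C | 0 by default |
| `noise_sd` | per-wavelength intensity noise | fraction of intensity scale | 0.01 |

The nonparametric analysis (`find_transition()`) does not assume this
model; the model is the generator's truth and the parametric estimator
(`fit_two_state()`), and the closed-form FWHM above is what lets the
nonparametric extraction be verified against it.

## Derivative analysis

`neg_derivative()` computes $-d\mathrm{GP}/dT$ by central finite
differences. For interior points the uneven-spacing stencil
$-(gp_{i+1} - gp_{i-1})/(T_{i+1} - T_{i-1})$ is used (exact for affine
GP, and for quadratics on uniform grids); the endpoints use one-sided
differences and carry a flag. Choices worth stating:

* **Endpoint handling.** One-sided endpoint values are retained in the
  derivative (they make the trapezoidal area telescope exactly — see
  below) but excluded from the peak search by default, because a
  one-sided stencil can manufacture a spurious edge maximum.
* **Peak location.** `t_m` is the grid argmax; ties break toward the
  lowest temperature. A three-point parabolic refinement is available
  behind `refine_peak = TRUE` but off by default, so that the reported
  value is always an acquired temperature.
* **FWHM.** Each half-maximum crossing is located by linear
  interpolation between the bracketing grid points, walking outward from
  the peak. A peak truncated by the grid on one side raises a typed
  error carrying the partial result rather than extrapolating a guess.
* **Area.** Trapezoidal integration over the full grid. On a uniform
  grid the central + one-sided scheme telescopes exactly:
  the area equals $\mathrm{GP}(T_{min}) - \mathrm{GP}(T_{max})$, which
  for a drift-free model on a grid spanning the transition approaches
  the plateau separation $g_{gel} - g_{fluid}$ — the package's
  (relative) enthalpy proxy. No calorimetric units are claimed.
* **No smoothing by default.** Replicate-averaged curves are
  differentiated as-is; a moving-average filter (`smooth_gp()`,
  `smooth_window =`) exists for noisy measured data and is recorded in
  the result's warnings when used.
* **Flat curves.** A derivative with no positive peak above `flat_tol`
  (default $10^{-8}$ GP/°C) raises a no-transition error; downstream
  tools (CLI included) turn that into a diagnostic rather than a number.

The analysis order is fixed: scans are averaged first, then GP is
computed, then replicates are aggregated. GP is a ratio, so
average-then-GP and GP-then-average differ in general; the package
follows the acquisition convention (average first) and a test documents
the inequality.

## The synthetic-spectra generator

`synth_spectrum()` builds each spectrum as a mixture of two Gaussian
bands centred at 440 nm (gel) and 490 nm (fluid). Because the bands
overlap, naive two-delta mixing would not give the requested GP; the two
band amplitudes are instead solved from the $2\times2$ linear system
that makes the noiseless intensities at exactly 440 and 490 nm satisfy
$\mathrm{GP} = \mathrm{GP}_{ideal}(T)$ while $I_{440} + I_{490}$ equals
the configured intensity scale. Gaussian noise of sd
`noise_sd * scale` is then added per wavelength and clipped at zero.

**Band width.** The default spectral standard deviation is 15 nm
(≈35 nm FWHM). With substantially broader bands the gel band's tail
slope at 490 nm exceeds the fluid band's flat top whenever the fluid
plateau is only modestly negative, pushing the mixture's maximum below
490 nm and breaking the canonical "peak at 490 in the fluid phase"
signature; 15 nm keeps the argmax on the band centres for every
packaged condition while remaining within the range of measured Laurdan
emission widths.

`synth_series()` reproduces the acquisition geometry: 400–540 nm in
1 nm steps, three raw scans averaged per steady-state spectrum, three
independent replicate samples, 1 °C temperature steps for the saturated
lipids (2 °C for POPC and soy polar extract, which are measured on
coarser grids). Every scan's noise stream is seeded deterministically
from the base seed and its (replicate, temperature, scan) indices, so
any subset of a series is reproducible in isolation and a regenerated
series is byte-identical after serialization.

**What is anchored and what is chosen.** Literature LUV transition
temperatures (24/41/54/−2 °C) and the 11 nm-disc shifts (+5 °C DMPC,
+2 °C DPPC, 0 °C DSPC) anchor the condition table. The 15 nm disc gets
the same shift as the 11 nm disc (experimentally indistinguishable), the
50 nm disc none, the 25 nm disc the midpoint. Widths implement the
qualitative cooperativity ordering — LUV sharpest (0.4 °C), discs
broader and strictly sharpening with size (3.0 → 1.0 °C for saturated
lipids) — and plateau levels (e.g. DMPC 0.55/−0.20) reflect typical
Laurdan contrast; these numbers are generator choices, stated once here
and overridable via the condition table or a run config. Soy polar
extract has no quantitative model: it is represented phenomenologically
as a plateau-offset, very-broad-pseudo-transition condition, and no
quantitative claim rests on it.

**What the generator does not emulate.** Solvent-relaxation
photophysics, excitation-wavelength dependence, dye partitioning between
phases or disc regions, scattering backgrounds, baseline drift, and
temperature-equilibration artifacts. Noise is independent Gaussian per
wavelength, clipped at zero; real detector noise is neither independent
nor Gaussian at low counts. Passing tests therefore certify the
*analysis chain* — averaging, GP, differentiation, peak extraction,
fitting — under controlled truth, not the behaviour of any particular
instrument.

## The boundary-lipid geometric model

Nanodisc rims perturb adjacent lipids. Treating the perturbed region as
a fixed-width annulus of width $w$ in a disc of diameter $d = 2r$, the
package provides two variants of the unperturbed fraction:

* **radius-ratio** (default): $(r - w)/r$;
* **area-ratio**: $((r - w)/r)^2$, the interior-to-total disc area.

The canonical unperturbed percentages for the four scaffold sizes —
77, 83, 90 and 95 % at 11, 15, 25 and 50 nm — are reproduced *exactly*
(77.27/83.33/90.00/95.00) by the radius-ratio form with a single width
$w = 1.25$ nm, which is therefore the default. They are **not**
consistent with the verbal picture of a ~1.5 nm (two-lipid-layer)
annulus under the area model: area-ratio with $w = 1.5$ nm gives 88 %
at 50 nm, and the width implied by the 50 nm value under area-ratio
(0.63 nm) yields 78 % at 11 nm. Both formulations are kept so users can
state either; the discrepancy is recorded here, not resolved. Nominal
diameters are used as bilayer diameters (no scaffold-belt subtraction),
and `predict_relative_area()` applies the two-population scaling (only
unperturbed lipids contribute to the transition area).

## Lipid-abundance normalization

`normalize_by_group_max()` divides every species intensity by the
maximum within its (sample, ion-mode) group — positive mode for PC,
negative for PA/PE/PI/PG and lysophospholipids — so the group reference
(e.g. PC 36:4, PI 34:2 in a typical soy polar mixture) is exactly 1.
The reference is computed as the group argmax rather than hard-coded; a
strict mode asserts expected reference labels. The operation is
idempotent and per-group scale invariant; cross-group ratios are
deliberately not preserved. `abundance_difference()` compares two
normalized tables (e.g. assembled nanodiscs versus the starting
mixture), with species missing from one table reported at relative
intensity 0 — how lysophospholipid depletion surfaces.

## Fitting

`fit_two_state()` estimates the two-state parameters by
Levenberg–Marquardt nonlinear least squares (via minpack.lm, which
converges cleanly on zero-residual data where Gauss–Newton
implementations stall). Initialization is deterministic: plateaus from
the curve extremes, $T_M$ from the derivative peak, $k$ from
FWHM$/2\ln(3+2\sqrt2)$, with midpoint/span fallbacks when the
nonparametric extraction fails. Parameters are box-bounded to their
physical ranges (plateaus in $[-1,1]$, $k > 0$, $T_M$ within an
expanded data span). Drifts are excluded by default
(`include_drift = TRUE` adds them) — fitting six parameters to a narrow
grid is poorly conditioned when the plateaus are barely sampled.

## Problem sizes and verification

The test suite generates everything it needs at run time: pipelines use
31–41-point 1 °C grids with three scans and one-to-three replicates;
closed-form checks (FWHM law, dense-grid argmax) use 0.01–0.05 °C
analytic GP grids; the parameter-recovery study runs 50 seeds at the
packaged noise level (`noise_sd = 0.01`) and checks the median absolute
$T_M$ error stays below half a degree — these sizes give sub-second to
few-second tests while leaving the statistical checks well-powered.
Independent oracles are used throughout: closed forms for the logistic
(midpoint, FWHM, limits), hand-evaluated stencils for the differences,
telescoping identities for the area, and direct evaluation of the
two-band mixture for the generator's GP round trip.

## Known limitations

* The two-state model is symmetric in temperature; asymmetric
  (pre-transition) features are not modelled and will bias $k$ slightly
  if present in real data.
* The enthalpy proxy is a relative GP-unit area; no conversion to
  calorimetric enthalpy is attempted.
* The boundary model is binary (perturbed/unperturbed); a perturbation
  continuum decaying from the rim — suggested by simulation work — is
  out of scope.
* Grid-argmax $T_M$ is quantized to the acquisition grid; use
  `refine_peak = TRUE` or `fit_two_state()` for sub-grid estimates.
* Complex mixtures (soy polar extract) are represented only
  phenomenologically; no mechanistic claims are supported for them.
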