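---
title: "Methods: drift-curve calorimetry, recombination corrections and the uncertainty budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drift-curve calorimetry, recombination corrections and the uncertainty budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashcal)
```

# The measurement problem

Reference dosimetry of ultra-high dose rate (UHDR) proton fields faces a
circular difficulty: the ionisation chambers used for routine reference
dosimetry need a large ion-recombination correction at ~63 Gy s⁻¹, and
the methods used to determine that correction disagree with each other
precisely in the regime where the correction is large. A graphite
calorimeter breaks the circle. It realises absorbed dose directly —
energy per unit mass appears as a temperature rise — and its response
does not depend on dose rate. `flashcal` implements the analysis on both
sides of that comparison.

# Quasi-adiabatic calorimeter analysis

## Model

In quasi-adiabatic operation the outer jacket is servo-stabilised a
little above room temperature (~298.2 K) while the core, thermally
isolated by vacuum gaps, drifts freely near 297.7 K. A sub-second
irradiation deposits ~10 mK. The analysis treats a run as three regimes:

1. a **pre-irradiation drift**, modelled as a quadratic polynomial in
   time (heat exchange with the jacket over a minute-scale window is
   smooth and slow; degree 2 captures its curvature without chasing
   noise);
2. the **irradiation window** (0.4–0.8 s), excluded from all fits;
3. a **post-irradiation drift**, again quadratic, beginning after a
   guard interval.

Both drifts are fitted by ordinary least squares and extrapolated to a
common evaluation time `t_eval`; the temperature rise is the offset

ΔT = post(t_eval) − pre(t_eval).

`t_eval` defaults to the midpoint of the irradiation window. For heat
deposited symmetrically in time (a good description of a near-constant
scanned delivery), linear heat-loss terms before and after cancel at the
midpoint, so this convention is exact to first order in the loss rate.
The drift offset itself is what the quantity *means* operationally:
where pre- and post-drift polynomials are identical up to a constant,
ΔT is independent of `t_eval` (a property the tests verify).

Dose follows the chain

D_core = c(T_eval) · ΔT,  D_w = D_core · k_imp · k_gap · s_w,g · k_fl · k_z,cal

with c(T) = 651.57 + 2.74 (T − 273.15) J kg⁻¹ K⁻¹ (an experimental
characterisation of the core graphite, valid over roughly room
temperature; the code enforces a (250, 350) K validity window) and the
five dimensionless factors supplied as configuration — they come from
Monte Carlo transport and analytic geometry, not from this package. The
chain identity D_w / D_core = Πk holds bit-for-bit by construction.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| fit window length | 60 | s | ~300 samples at 5 Hz: small drift-model bias, ~10 µK statistical error on the extrapolation |
| guard after beam-off | 2 | s | lets heat redistribute between core and impurities before the post drift is fitted |
| drift degree | 2 | – | the conventional drift model; exposed for sensitivity studies |
| `t_eval` | mid-irradiation | s | exact for symmetric deposition (above) |
| T for c(T) | pre-drift at `t_eval` | K | the choice changes c by < 0.01% across the ~10 mK ambiguity, so any sensible convention is equivalent |

Negative or zero ΔT is returned with a warning flag rather than an
error: background and no-beam runs are legitimate analyses.

## Numerical choices

Drift polynomials are fitted in time centred on the fit-window midpoint.
On a 297.7 K carrier, fitting raw powers of absolute run time degrades
the extrapolated offset; centring keeps the noiseless round trip
(construct trace → fit → extract) below 10⁻¹⁰ K, the exactness bound the
test suite enforces. `drift_coefficients(model, origin = 0)` rebases to
absolute-time coefficients when the polynomial itself is wanted.

The arithmetic chain is exactly invertible: dose → ΔT → dose closes to
double-precision rounding (≲10⁻¹⁵ relative), which the acceptance script
reports. A fit-based round trip cannot reach that level — merely storing
297.7 ± noise as doubles injects ~3×10⁻¹⁴ K per sample — hence the two
different closure bounds.

# Chamber dose and recombination

The chamber chain is the standard reference-dosimetry product
D_w = M · k_TP · k_elec · k_pol · k_ion · N_D,w · k_Q, with
k_TP = (T/T_ref)(P_ref/P) resolved per chamber from its calibrating
laboratory (293.2 K for NPL-issued, 295.2 K for NIST-issued
calibrations, both 1013.3 mbar) and
k_pol = (|M₊| + |M₋|)/(2|M_op|). Voltages are stored signed (the
benchmark operating point is −400 V, collecting negative charge); all
recombination arithmetic uses magnitudes. `k_elec` defaults to 1.

## Beam classification

General recombination in a continuous beam follows, near saturation,
1/M = 1/M_sat · (1 + ξ²/V²); in a pulsed beam the correction is linear
in 1/V. `jaffe_classify()` fits both forms to the reciprocal curve and
declares the beam continuous when the quadratic term (a) reduces the
linear fit's residual sum of squares by more than 50% — a deliberately
coarse threshold, since the two hypotheses differ grossly when either is
true — and (b) has a positive coefficient. A linear fit whose residual
is already at numerical roundoff short-circuits to "pulsed", so exact
pulsed-model data cannot be misclassified on the strength of a
meaningless RSS ratio.

## Two-voltage vs three-voltage

The two-voltage continuous expression
k_ion(V₁) = (r² − 1)/(r² − M₁/M₂), r = V₁/V₂, is *analytically exact*
when the pure general-recombination model holds — the tests verify this
identity to 10⁻¹⁰ over random parameter sets. Its weakness is model
error: any non-quadratic contribution to 1/M(1/V), such as initial
recombination (a 1/V term), biases it, and the bias grows with the size
of the correction.

The three-voltage method fits 1/M = a + b/V + c/V² through the
`n_points` highest voltages of a measured saturation curve (exact solve
at 3 points, least squares for more), giving M_sat = 1/a and
k_ion(V_op) = (a + b/V_op + c/V_op²)/a. Fitting *at higher voltages*
keeps the data where the near-saturation expansion is valid; for a
three-point solve at voltages V₁ > V₂ > V₃ the intercept bias from an
unmodelled cubic term with coefficient β₃ is exactly β₃/(V₁V₂V₃), which
is why raising the fit voltages suppresses it so effectively.

There is a genuine bias–variance trade-off: the exact 3-point solve is
noise-fragile (the intercept is an extrapolation to 1/V = 0), so for
noisy curves a least-squares fit over more of the high-voltage end
(e.g. `n_points = 7` over a 50–600 V ladder, i.e. 300–600 V) is the
recommended operating point, and is what the package's own
method-comparison uses.

# Synthetic data: what it emulates, and what it does not

`gen_calorimeter_trace()` builds a trace as pre-drift polynomial +
linear intra-irradiation ramp + post-drift polynomial + white Gaussian
noise (default 50 µK, consistent with a sensing chain specified as
better than 100 µK). The true step is back-computed from the target
dose through the same c(T) and factor chain the analysis applies, so
noiseless closure is exact by construction. Two modelling notes:

* the intra-irradiation shape is a linear ramp; midpoint extrapolation
  is insensitive to this choice by construction;
* the post-drift slope change (cooling onset) is anchored at the
  evaluation midpoint, so the recipe's "truth" is exactly the quantity
  the midpoint-extrapolation convention estimates. Anchoring at beam-off
  would fold half a delivery time of the new slope into the truth and
  make the generator and the estimator answer subtly different
  questions.

`gen_saturation_curve()` uses
M(V) = M_sat · [1/(1 + A/V)] · [1/(1 + ξ²/V²)] · (1 + mV) · (1 + ε):
general recombination (ξ²), initial recombination (A), an optional
charge-multiplication excess (m, default off — real small-gap chambers
show it at high voltage, and as in practice the estimators never correct
for it), and multiplicative noise. The truth function deliberately
excludes the multiplication term: k_ion corrects collection *losses*.

What the generators do **not** emulate: correlated (1/f) temperature
noise, inter-run thermal memory (each run is an independent reset,
matching a 2-minute repetition cadence), beam temporal microstructure,
spot-scanning spatial patterns, and drifts that are not low-order
polynomials. Passing tests therefore demonstrate correctness of the
*analysis* under its stated model, not robustness to every instrumental
pathology.

## Study conditions frozen in the tests

* **Repeated-run recovery**: 50 replicate series of 20 runs with 0.18%
  inter-run dose scatter and zero trace noise, checking the Type A
  relative SE against 0.18%/√20 ≈ 0.04%. Trace noise is off because the
  condition being tested is "the per-run scatter *is* 0.18%"; with the
  default 50 µK noise the drift-fit extrapolation adds a comparable
  ~0.13% of its own (two quadratic extrapolations of ~9 µK noise each
  against a 9.9 mK step), which is a statement about the noise
  propagation, tested separately as an unbiasedness property.
* **Method divergence**: 200 seeds with A ~ U(10, 40) V, true
  k_ion(400 V) in [1.05, 1.25], per-point noise 5×10⁻⁴ (a mean of ~20
  repeats at ~0.2% per-shot repeatability), two-voltage pair
  400/200 V, three-voltage fit over 300–600 V. The initial-recombination
  strength is set so the two methods diverge by the few-percent level
  observed for large-volume chambers at UHDR; the criterion asserts the
  three-voltage estimate is closer to truth in ≥95% of seeds for
  corrections above 5%.
* Problem sizes throughout (240 s runs at 5 Hz, 100–200 seed loops,
  10⁶-draw Monte Carlo oracle for the triangular SD) are chosen so the
  whole suite runs in a few seconds while keeping sampling error an
  order of magnitude below each asserted tolerance.

# Uncertainty budget

Components are labelled relative uncertainties in percent, Type A
(statistical) or Type B (other), treated as uncorrelated and combined in
quadrature; the overall standard uncertainty combines the two unrounded
totals. Printed-precision policy: column totals to 2 decimals, overall
to 1 decimal. Upper-bound entries ("< 0.01") participate at their bound
value by default (conservative); using zero instead changes no rounded
total of the shipped budget, and both behaviours are tested. The shipped
`calorimeter_budget()` combines to 0.24% (Type A) and 0.845% (Type B) —
note the Type B quadrature of the *printed, rounded* components rounds
to 0.85, and since the unrounded source components are not public the
package reports its own computation rather than forcing the tabulated
0.84 — and 0.9% overall at 1σ, in line with the ~1% recommendation for
reference dosimetry.

Interval-type Type B information (for instance the spread between two
Monte Carlo codes' fluence-correction estimates) is converted to a
standard uncertainty with `triangular_std_uncertainty()`, the closed
form of the (possibly asymmetric) triangular distribution's SD, verified
in the tests against a 10⁶-draw inverse-CDF sampling oracle.

# Known limitations

* Quasi-adiabatic mode only; active-isothermal operation is not
  modelled.
* No heat-transfer simulation between calorimeter components: the guard
  interval and drift model absorb those effects empirically.
* The three-voltage functional form (quadratic in 1/V through the
  high-voltage points) is a documented convention consistent with the
  continuous-beam Jaffé behaviour; other fit forms exist in the
  literature.
* Correction factors and calibration coefficients are inputs. The
  shipped chamber registry carries placeholder N_D,w and k_Q values
  flagged as non-physical; real values come from calibration
  certificates and k_Q tables.
* Pulsed-beam (dose-per-pulse) recombination models for electron FLASH
  are out of scope: the estimators here assume the continuous-beam
  regime that scanned proton delivery produces.
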