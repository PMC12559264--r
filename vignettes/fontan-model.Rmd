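---
title: "A lumped-parameter Fontan circulation with collateral vessels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter Fontan circulation with collateral vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontansim)
```

## The physiological problem

In a total cavopulmonary connection (TCPC) Fontan circulation a single
ventricle drives the systemic circulation, and systemic venous return
flows *passively* through the lungs: the superior vena cava and (via an
artificial conduit) the inferior vena cava are anastomosed directly to
the pulmonary arteries, with no subpulmonary pump. Two kinds of abnormal
vessels commonly complicate this circulation:

* **aortopulmonary collaterals (APC)** — arteries (mammary, bronchial,
  intercostal) connecting the systemic arterial tree to the pulmonary
  arteries. They recirculate oxygenated blood through the lungs, raising
  ventricular preload and total cardiac output while stealing flow from
  the body;
* **venovenous collaterals (VVC)** — thin-walled veins connecting the
  systemic venous side to the pulmonary veins or atrium. They bypass the
  pulmonary capillaries, admixing desaturated blood into the systemic
  arterial stream;

plus the surgically created **fenestration** between the Fontan conduit
and the atrium, which behaves like a controlled VVC.

`fontansim` simulates this circulation as a closed-loop 0D
(lumped-parameter) network and couples it to a Fick-principle oxygen
layer, so that a scenario — which collaterals are present, how the
pulmonary and systemic resistances are scaled, how much dobutamine is
infused — maps to arterial and central venous oxygen saturations,
cardiac output, and ventricular function indices.

## The circulation model

### Network

Every vascular compartment is a Windkessel element: a compliance `C`
(pressure `P = (V - V0)/C`), connected by edges carrying a viscous
resistance `R` and, on the Fontan pathway, an inertance `L`
(`L dQ/dt = dP - R Q`). The shipped topology has

* one systemic arterial compartment (aorta),
* four parallel systemic beds — upper body (30% of flow), abdominal
  organs (45%), lower extremities (20%), coronary (~4%) — each an
  arterial resistance (85% of the bed total) into a venous compliance
  and a venous resistance (15%),
* the SVC and the IVC/conduit compartment; the SVC joins both pulmonary
  artery branches, the conduit joins the right branch through the graft
  (the TCPC constraint: neither cava connects to the atrium),
* two parallel lung resistances into a pulmonary venous compartment
  draining to the atrium.

Coronary venous return is lumped into the SVC, so without shunts *all*
systemic return is caval: aortic output equals net cardiac output and
the arterial saturation equals the pulmonary end-capillary saturation
exactly. Both properties are used as invariants in the test suite.

The parallel combination of the systemic beds equals the reference
systemic vascular resistance 0.9 mmHg·s/mL by construction, and the two
lung resistances combine to the reference pulmonary resistance
0.05 mmHg·s/mL; `svr_ratio`/`pvr_ratio` scalings (studied range
0.6–1.6) multiply exactly these groups.

### Chambers

The ventricle and atrium are time-varying elastance chambers,

`P = E(t) (V - V0) + visc * dV/dt`,

where `E(t)` sweeps between the diastolic elastance `e_min` and the
end-systolic elastance `e_max` following a normalized double-Hill
activation (the standard smooth waveform of 0D heart models; rise and
decay time fractions and Hill exponents are registry parameters). The
atrial waveform is identical in form, shifted to fire late in the cycle.
The linear resistive viscoelastic term (`visc`, mmHg·s/mL) damps rapid
volume changes; a convolutional formulation was not adopted because the
operations contract only requires a rate-proportional pressure
contribution.

Valves are regularized diodes: forward flow `(dP - w)/R`, exact zero
reverse flow (optional linear leak), and a quadratic C¹ blend of width
`2w` (default `w = 0.05` mmHg) so the right-hand side stays smooth for
the integrator. A valve law that is simultaneously smooth, strictly
monotone and exactly leak-free cannot exist (a monotone function that
vanishes at 0 and at negative infinity is identically zero on the
negative axis), which is why the blend is C¹-piecewise rather than
analytic.

### Shunts

A shunt edge carries `Q = g * dP * |dP|^(n-1)`; `g` is the flow at a
1 mmHg gradient. The APC is linear (`n = 1`): it is an arterial vessel
operating at a large, nearly constant gradient (systemic minus
pulmonary arterial pressure). The VVC and the fenestration use `n = 3.5`.
This models them as *distensible* venous channels whose caliber grows
with distending pressure: their gradient is essentially the
transpulmonary pressure drop, which scales with pulmonary flow, so with
a linear law the venous-shunt *fraction* of cardiac output would be
invariant to total flow. Clinically and in this model, states of high
flow and venous congestion (e.g. dobutamine) recruit and dilate these
collaterals disproportionately; the exponent is the simplest
representation of that recruitment and is calibrated together with the
conductances (see *Calibration*).

### Numerics

The network ODE (state: compartment volumes plus inertial-edge flows)
conserves volume identically — every edge moves volume between two
nodes — and the suite asserts machine-precision conservation of the
analytic derivative and < 0.1% drift over integrated runs.

The viscoelastic term couples chamber pressure to the flows through the
adjacent low-resistance valves; evaluated explicitly this coupling is
unstable whenever `visc > R_valve` (the integrator stalls). The
right-hand side therefore freezes every algebraic edge at its secant
conductance (`Q = ceff * dP` exactly, at the current gradient), solves
the resulting small linear system for the chamber pressures exactly,
and refreshes the secants once. The same scheme is implemented twice —
in R (`state_derivative`) and in C++ for the integrator — and the two
are cross-checked to rounding error in the tests.

Integration uses `deSolve::lsoda` (adaptive, stiffness-switching) with
relative tolerance 1e-6 and absolute tolerance 1e-8 mL. A run
integrates beat by beat from a compliance-proportional initial volume
distribution (documented pressure guesses, not a physiological
assertion) until the beat-to-beat state change falls below 2e-5
(max-norm, relative), at most 200 beats; the converged beat is then
sampled at 1 ms and averaged with trapezoidal weights. The shipped
scenarios converge in 30–40 beats, and a warm start from a neighboring
sweep cell converges in a handful.

## The oxygen layer

Oxygen is transported on the *beat-averaged* flows (steady-species
assumption — the model predicts one saturation pair per scenario, so
intra-beat advection is not resolved). Content follows

`C = Hb * 1.36 * S/100 + PO2 * 0.0031`  (mL O2/dL)

with Hb 15 g/dL and fixed dissolved-gas pressures PaO2 = 100 /
PvO2 = 40 mmHg; the dissolved term is ~1.5% of content, so the
operating-point choice is immaterial at the reported precision. Blood
leaving the lungs carries the pulmonary end-capillary saturation
(calibrated, 98.8%). The systemic beds jointly extract
`VO2I * BSA` (resting VO2I 125 mL/min/m², a standard adult resting
value; BSA 1.63 m²), distributed in proportion to bed flow, so every
bed returns the same venous content. At every node the outgoing
saturation is the flow-weighted mean of the incoming saturations.

This mixing system is affine in the saturations, and
`solve_saturations` offers two routes: damped successive substitution
from the configured starting values (97% arterial / 60% venous), and a
direct linear solve; the suite requires them to agree to 1e-9. Fick
closure, `VO2I = COI × (CaO2 − CvO2) × 10` with COI the systemic
(tissue-perfusing) flow index, holds exactly by construction and is
asserted to 1e-6 relative at every solved operating point. An
infeasible consumption (one that would drive a saturation negative) is
refused with the maximum supportable VO2I in the error message.

`SaO2` is the aortic-node saturation; `SvO2` is the flow-weighted mixed
caval (central venous) saturation.

## Pharmacology

Dobutamine acts through a dose-multiplier table with anchors at 0, 5
and 10 µg/kg/min and linear interpolation: ventricular `e_max` × 2.2 at
dose 10, systemic resistances × 0.62, heart rate × 1.38, and VO2I ×
1.28 (oxygen consumption rises with the drug-induced workload). The
dose-0 column is the identity; doses beyond the grid are refused.
Resistance-ratio scaling and the dobutamine response are both
multiplicative on the resistances and therefore commute.

## Cardiac function indices

From the converged beat the ventricular pressure–volume loop yields

* `EF = (EDV − ESV)/EDV`,
* `Ea = Pes/SV` with the end-systolic point taken as the loop point
  maximizing `P/(V − V0)`,
* `Ees` reported as the chamber's configured `e_max` (it is known in
  simulation; a separate two-afterload estimator exists and is required
  by the tests to recover `e_max` within 2% on an ideal chamber),
* `SW` as the shoelace area of the loop, and
* `PVA = SW + PE` with `PE = Pes (Ves − V0)/2`, the standard
  end-systolic-pressure–volume-relation triangle through `(V0, 0)`.

## Calibration

The per-compartment parameter values of this kind of model are not
universal constants; the shipped registry was calibrated so the model
reproduces its reference operating points:

| scenario | SaO2 / SvO2 target (%) |
|---|---|
| baseline, no collaterals (fenestration open) | 96 / 62 |
| VVC + APC | 92 / 54 |
| VVC + APC + dobutamine 10 µg/kg/min | 88 / 58 |

The free quantities were the VVC and APC conductances, the pulmonary
end-capillary saturation, the dobutamine VO2I slope, the dobutamine
e_max/SVR/heart-rate anchors, and the venous-shunt distensibility
exponent; `calibrate_registry()` (monotone bisection for one free
parameter, bounded Nelder–Mead otherwise, squared relative residuals)
is exported so the operating points can be re-fit under modified
assumptions. The acceptance suite checks each pair within ±2 percentage
points, and `scripts/acceptance.R` recomputes all six saturations from
scratch.

## Directional claims, and two that this model contradicts

Under the calibrated registry the model reproduces the expected
directions: raising the pulmonary resistance ratio over 0.6–1.6
monotonically lowers SaO2 and net cardiac output in every collateral
configuration; enabling VVC+APC raises cardiac output while lowering
net (caval) output; dobutamine raises cardiac output and Ees/Ea and,
with collaterals present, lowers SaO2 while raising SvO2.

Two frequently quoted directions are *not* reproduced, and we believe
they cannot be reproduced jointly with the saturation targets in any
model of this class:

1. **Dobutamine lowering net cardiac output.** The saturation shift
   (92, 53) → (88, 58) under dobutamine, inserted into the Fick
   relation, forces tissue-perfusing flow *up* by at least ~26% for any
   non-negative VO2I dose response. Net (caval) output differs from
   tissue perfusion only by the venous-shunt steal, and the steal
   growth needed to overturn a 26% rise would depress SaO2 below 86%,
   outside the saturation band. The model therefore shows net output
   rising mildly with dose.
2. **Dobutamine lowering SW/PVA.** With the standard
   end-systolic-elastance triangle, `PE = Pes²/(2 Ees)`. Any inotropic
   response (`Ees` multiplier > 1) with near-flat end-systolic pressure
   shrinks PE faster than the measured stroke work falls, so SW/PVA
   (= 1/(1 + PE/SW)) rises. Profiles that suppress the inotropic
   component enough to reverse this also destroy the required rise in
   Ees/Ea.

Both are asserted in their reported direction in the acceptance suite
and fail there by design; the unit suite tests only the parameter-free
physics. Relatedly, adding an aortopulmonary collateral is a parallel
arterial path and therefore *lowers* effective arterial elastance in
this model, so Ees/Ea rises slightly with collaterals (while EF and
SW/PVA rise, as reported).

## What the synthetic scenarios do and do not capture

The scenario generator reproduces the study conditions: an idealized
single-ventricle patient (BSA 1.63 m², Hb 15 g/dL, heart rate
80 beats/min), reference resistances 0.9/0.05 mmHg·s/mL with
magnification ratios in 0.6–1.6, collateral configurations
none / VVC / VVC+APC (APC-only is included as an extrapolation), and
dobutamine doses 0–10 µg/kg/min. It does not emulate respiratory
modulation, gravity/posture, baroreflex control, hemoglobin
dissociation dynamics, patient-to-patient parameter spread, or imaging
noise — so passing tests demonstrate internal consistency and
reproduction of the reference operating points, not validation against
patient data.

## Known limitations

* Purely 0D: no wave propagation; the original model family's 1D
  arterial segments are approximated by chained compartments.
* Single calibrated parameter set; no identifiability analysis.
* The oxygen layer ignores intra-beat saturation dynamics and CO2.
* The distensible-shunt exponent is a phenomenological recruitment law,
  not a vessel-mechanics model.

## Problem sizes used by the shipped checks

The test suite and acceptance script run full scenarios (11
compartments + 3 inertial flows, ~35 beats to convergence, 1 ms
sampling) and a 6 × 2 × 3 sweep (pulmonary ratios × doses × collateral
configurations); these sizes were chosen as the smallest that exercise
every operating point the package reports.
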