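---
title: "Models and methods: adaptive ventilation by least work and by minimal inspiratory power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: adaptive ventilation by least work and by minimal inspiratory power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivent)
```

## The two selection equations

Adaptive pressure-controlled modes deliver a clinician-set minute
ventilation $\dot V_E$ and choose the split into respiratory rate RR and
tidal volume $V_T = \dot V_E / \mathrm{RR}$ automatically. Two selection
principles are implemented, both solved as fixed points in coherent units
(RR in breaths/s, $\dot V_E$ in ml/s, dead space $V_{D_A}$ in ml, the
expiratory time constant $RC_e$ in s):

* **AVM** — Otis' least-work-of-breathing equation (derived for sinusoidal
  spontaneous breathing):
  $$\mathrm{RR} = \frac{\sqrt{1 + 4\pi^2\,RC_e\,(\dot V_E -
  V_{D_A}\mathrm{RR})/V_{D_A}} - 1}{2\pi^2\,RC_e}.$$
* **AVM2** — minimization of *inspiratory power*, the pressure-volume-loop
  area of an ideal square-wave breath times the rate,
  $P = \mathrm{RR}\,\Delta P\,V_T$. With the inspiratory time set to half
  the cycle and alveolar ventilation held fixed, stationarity of $P$ in RR
  gives
  $$\mathrm{RR} = \frac{\dot V_E}{2 V_{D_A}}
  \left(1 - \frac{1}{2\,\mathrm{RR}\,RC_e\,
  \bigl(e^{1/(2\,\mathrm{RR}\,RC_e)} - 1\bigr)}\right),$$
  whose bracketed correction factor lies strictly in $(0,1)$; hence the
  AVM2 rate is always below $\dot V_E/(2V_{D_A})$ and the delivered $V_T$
  always exceeds $2V_{D_A}$.

The published rendering of the AVM2 exponent is typographically ambiguous;
the form above is the one whose fixed point provably coincides with the
stationary point of the square-wave power objective, and `power_curve()`
verifies that equivalence by brute force (grid argmin within 0.05/min of
the fixed point across $\dot V_E \in [5,15]$ l/min, $RC_e \in [0.3,1.5]$ s,
$V_{D_A} \in [110,220]$ ml).

Both maps share the limit $\dot V_E/(2V_{D_A})$ as $RC_e \to 0$. For large
$RC_e$ the AVM2 fixed point approaches
$\sqrt{\dot V_E/(8 V_{D_A} RC_e)}$ *from below*, with relative deviation
$1/(12x)$, $x = 2\,\mathrm{RR}\,RC_e$: at $RC_e = 50$ s and cohort-typical
$\dot V_E/V_{D_A}$ this deviation is still 1.9%, a slow $O(x^{-1})$
approach worth knowing when using the asymptote as a check.

The solver is a damped fixed-point iteration
$x_{k+1} = (1-\lambda)x_k + \lambda f(x_k)$ with $\lambda = 0.5$ (plain
iteration of the AVM2 map oscillates), started at 15/min, tolerance
$10^{-9}$ breaths/s, at most 500 iterations, with a bracketed `uniroot`
fallback on $g(x) = x - f(x)$. The Otis map uses
$\sqrt{1+\varepsilon}-1 = \varepsilon/(\sqrt{1+\varepsilon}+1)$ to stay
accurate as $RC_e \to 0$. Rates outside the solver bounds (default 4–60
breaths/min) are clamped and flagged; the commercial devices' further
safety envelopes are not public, so none are invented beyond the
inspiratory-pressure clamp and the expiratory-time protection below.

## The lung model and the 100-Hz waveform

The plant is a linear one-compartment respiratory system with separate
inspiratory and expiratory resistances: inflation toward
$\Delta P\,C_{rs}$ with $\tau_i = R_{insp} C_{rs}/1000$ under a square
(optionally linearly rising) pressure wave, passive exponential expiration
with $\tau_e = RC_e$. The per-breath end-expiratory volume map is affine,
so its cyclic steady state — including trapped volume and the resulting
auto-PEEP whenever the expiratory time is much less than about
$5\tau_e$ — is the closed-form fixed point of a geometric series; phases
are simulated directly at that steady state. Endpoints are averaged over
the last 5 min of a phase, which at cyclic steady state equals any window,
so one hour of ventilation is simulated compressed (the metrics window
plus a terminal 2.5-s hold maneuver, the midpoint of the protocol's
2–3 s). Sampling is fixed at 0.01 s to match the ventilator recording;
metrics never assume finer resolution.

Because the idealized square-wave flow is discontinuous at phase
transitions, tidal volumes and the pressure-volume work integral are read
from the integrated volume channel (which carries the exact inspiratory
peak) rather than from a time-trapezoid of flow across the transition;
within each breath phase the volume channel and the trapezoidal flow
integral agree to well under 0.5 ml.

## Measured endpoints

* Static driving pressure: plateau (mean airway pressure over the final
  0.5 s of a ≥2-s zero-flow hold) minus **set** PEEP. Referencing to set
  PEEP means auto-PEEP contaminates $\Delta P_{stat}$ upward; the
  simulator exposes the true auto-PEEP as a diagnostic attribute rather
  than silently correcting the measurement, because that is what the
  clinical maneuver actually reports.
* Static compliance: expired $V_T / \Delta P_{stat}$. Under heavy
  trapping this *understates* true compliance by the factor $(1-b)$,
  $b = e^{-T_e/\tau_e}$ — an emergent measurement artifact, not a model
  input, and the mechanism by which the lower measured compliance during
  power-minimized ventilation arises here.
* Mechanical power: per breath, the trapezoidal integral of absolute
  airway pressure over inspired volume (PEEP included, matching the
  magnitude of reported total power), averaged over regular breaths and
  multiplied by the measured rate.
* Expiratory time constant: least-squares slope (with intercept) of
  expiratory volume against flow over the 75%→25% expired-volume window.
  For a single-compartment expiration the intercept absorbs the trapped
  volume, so the estimate is exact even on truncated expirations; a flag
  is raised when end-expiratory flow still exceeds 5% of peak.
* Bohr dead space $V_D = V_T (Pa_{CO_2} - P_{E,CO_2})/Pa_{CO_2}$ and
  alveolar ventilation $\dot V_A = (V_T - V_D)\,\mathrm{RR}$. The
  estimator is agnostic to which expired CO$_2$ tension is supplied; the
  trial feeds the mixed-expired tension reconstructed from the gas model
  (series dead space 2.2 ml/kg PBW plus an alveolar dead-space fraction),
  which recovers physiological dead space the way volumetric capnography
  would and yields $V_D/V_T \approx 0.4$, the magnitude implied by the
  reported alveolar ventilation. An end-tidal tension may be supplied
  instead, but with a patient-constant arterial–end-tidal gradient that
  estimate tracks minute ventilation rather than alveolar ventilation and
  systematically separates the two modes.

## The closed loop

Each control step selects RR by the mode's equation from the measured
time constant, sets $V_T = \dot V_E/\mathrm{RR}$, fixes the inspiratory
time by the I:E rule, and applies the inspiratory pressure that delivers
the target $V_T$ at the plant's cyclic steady state — the volume-targeting
servo that adaptive pressure modes run breath by breath (equivalently:
the naive pressure formula evaluated with the auto-PEEP-biased *measured*
compliance, which self-corrects almost exactly).

I:E rules: AVM grants three expiratory time constants, with the
inspiratory fraction clamped to $[1/4, 1/3]$ of the cycle — at
cohort-typical mechanics this reproduces the observed I:E near 1:2. AVM2
uses half the cycle (the assumption under which its objective is derived)
shortened when needed by the expiratory-time protection
$T_e \ge 2\,RC_e$, the standard safety rule of this mode family; the
resulting cohort-mean I:E is near the observed 1:1.1, and wherever the
protection binds the trapped fraction is pinned at $e^{-2}$, keeping the
compliance-measurement artifact uniform across patients.

The %MinVol loop holds end-tidal CO$_2$ at its baseline value under the
steady-state alveolar ventilation equation
$Pa_{CO_2} = 0.863\,\dot V_{CO_2}/\dot V_A$: outside the protocol's
±2 mmHg band the banded rule steps the target minute ventilation by ±10%
(range 25–350%); inside the band a proportional titration (capped at the
same step size) trims etCO$_2$ to within 0.1 mmHg of baseline. The band
and step are protocol constants; the titration tolerance is a numerical
convergence parameter of the emulation — the protocol's stated intent is
to keep etCO$_2$ constant, and the in-model etCO$_2$ signal is noise-free.
Tight titration is what guarantees per-patient alveolar-ventilation
equality between a patient's two phases (worst case
$2\times0.1$ mmHg $/ 30$ mmHg $< 1\%$), and the loop converges in
well under 20 adjustments for every eligible cohort patient.

## The synthetic cohort

Marginals are truncated normals calibrated to the study population:
compliance 55 ± 13 ml/cmH$_2$O (ARDS subgroup 47 ± 9), expiratory time
constant 0.82 ± 0.22 s (ARDS 0.73 ± 0.18) truncated at the 1.5-s
eligibility bound, inspiratory resistance 11.1 ± 2.3 cmH$_2$O·s/l,
predicted body weight 74 ± 10 kg, baseline $V_T$ 7.5 ± 0.8 ml/kg at
15.3 ± 1.8 breaths/min, PaCO$_2$ 43 ± 6 mmHg, PEEP discrete with median 8
and IQR 8–10 cmH$_2$O. CO$_2$ production is derived per patient so that
the baseline alveolar ventilation reproduces the sampled PaCO$_2$; the
arterial–end-tidal gradient (4 ± 2 mmHg) and the alveolar dead-space
fraction (0.15 ± 0.07) are sampled where the study reports no value, at
magnitudes standard for ventilated ICU patients.

Compliance and time constant are coupled by a Gaussian copula with
correlation 0.85. The study's own data demand a coupling at least that
strong: the reported correlation of 0.86 between delivered $V_T$ and
measured compliance under power minimization is bounded above by the
compliance–time-constant correlation, since the selection equations see
compliance only through $RC_e$. The implied expiratory resistance
$1000\,RC_e/C_{rs}$ then stays in the physiological 11–20 cmH$_2$O·s/l
range.

The only within-patient noise is arterial blood-gas sampling error on
recorded PaCO$_2$ (SD 1.5 mmHg, typical analyzer repeatability), drawn
per patient and mode — never per phase order, so phase order has exactly
zero effect and the cross-over is carryover-neutral by construction. No
phase-level jitter is imposed on the mechanics: a linear time-invariant
lung cannot genuinely change compliance between modes, and independent
per-phase jitter would wash out the tidal-volume–compliance correlation
structure the trial is meant to exhibit.

## What the emulation shows — and what it cannot

On 20-patient synthetic cohorts the cross-over engine reproduces, with
the study's own paired-test rules (D'Agostino–Pearson normality on the
differences deciding paired *t* versus exact Wilcoxon, no multiplicity
correction, as in the study): lower $V_T$/kg and static driving pressure
under power minimization, higher rate and mean airway pressure, and no
alveolar-ventilation difference. The design sample size (20 pairs for
1 ml/kg at SD 1.5, 80% power, two-sided 5%) is recomputed exactly from
the noncentral *t*.

Two reported contrasts do **not** emerge from the printed equations plus
the linear lung, and are documented rather than forced:

* *Mechanical power.* The pure power-minimization fixed point selects
  rates around 18–19/min where the commercial device chose 15.8 — the
  printed equation applied to the printed cohort parameters yields 18.0,
  so the device evidently applies additional undisclosed rules. The
  resulting rate gap doubles the dead-space reventilation cost
  ($\mathrm{PEEP}\cdot V_{D_A}\cdot\Delta\mathrm{RR}$) and, at two time
  constants of expiration, auto-PEEP inflates the delivered pressure by
  about 1.4 cmH$_2$O; together these slightly outweigh the square-wave
  objective's intrinsic advantage, so measured total power comes out
  marginally (~2%) *higher* under power minimization here, not ~10%
  lower as reported.
* *Correlation contrast.* The tidal-volume–compliance correlation is
  higher under power minimization only by ~0.01–0.02 in this model (the
  two equations' $V_T$–$RC_e$ elasticities after dead-space feedback are
  nearly equal), far below the sampling noise of a correlation difference
  at $n = 20$; the reported 0.86-vs-0.57 contrast implies a roughly
  twice-stronger coupling in the device than the printed equation
  produces.

Passing the synthetic trial therefore validates the computational chain —
equations, simulator, metrics, controller, statistics — under the linear
single-compartment idealization with parameter magnitudes of the study
population. It does not validate nonlinear-lung behaviour (recruitment,
overdistension), oxygenation or hemodynamic responses, spontaneous
breathing (excluded by the study), or the undisclosed rule set of the
commercial implementations.

## Numerical choices and degenerate inputs

Problem sizes were chosen for desk-scale reproducibility: phases are
simulated as their final 5-min window (~70–110 breaths at 100 Hz) plus
the hold maneuver; the directional and correlation checks use ten master
seeds of 20 patients. Degenerate inputs fail loudly: non-positive
ventilation targets, inadmissible fixed points (alveolar ventilation not
positive), settings without positive expiratory time, holds outside
2–3 s, expired-CO$_2$ tensions above arterial, dead space above tidal
volume, infeasible cohort truncations (a time-constant mean beyond the
eligibility bound exhausts the 1000-draw rejection budget). Ties and
zero differences in the Wilcoxon branch are dropped with the exact
distribution used up to 25 non-zero pairs.
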