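---
title: "Circadian gating of the cell cycle and the timing of phase-specific chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian gating of the cell cycle and the timing of phase-specific chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocycle)
```

## The model

`chronocycle` simulates a linear population of proliferating cells divided
into four cell-cycle compartments: G0/G1, S, G2 and M.  The G0/G1 phase has
an exponentially distributed duration with exit rate $\kappa(t)$; the S, G2
and M phases are deterministic transit compartments of durations $T_S$,
$T_{G2}(t)$ and $T_M$.  The circadian clock enters in two places, both as
imposed sinusoids (there is no mechanistic clock-gene model):

$$\kappa(t) = \bar\kappa\left[1 + a_\kappa \cos\frac{2\pi (t -
t_\kappa)}{24}\right], \qquad
T_{G2}(t) = \bar T_{G2}\left[1 + a_{G2} \cos\frac{2\pi (t -
t_{G2})}{24}\right].$$

This mirrors the physiology of clock-gated S-phase entry (MYC/cyclin-D1
driven G1--S commitment) and the WEE1-gated G2--M transition.  Cells in
G0/G1 can also leave permanently at a rate $\gamma$ (differentiation,
quiescence loss), and each downstream phase carries a basal apoptosis rate
$d_S$, $d_{G2}$, $d_M$.  At the end of M the cell divides into two G0/G1
cells.

Writing $F(t) = \kappa(t)N_{G1}(t)$ for the S-entry flux and $T(t) = T_S +
T_{G2}(t) + T_M$ for the total S+G2+M transit attributed to the cohort
*dividing* at $t$, the G0/G1 balance closes on itself:

$$\frac{dN_{G1}}{dt} = -\big(\kappa(t) + \gamma + d_{G1,drug}(t)\big)
N_{G1}(t) + 2\,\big(1 - T'(t)\big)\,\sigma(t)\,F\!\big(t - T(t)\big).$$

The factor 2 is the doubling at division; $(1 - T'(t))$ is the cohort
Jacobian that keeps cell numbers conserved while the transit time itself
oscillates (without it, division and entry fluxes would disagree whenever
$T_{G2}$ is rising or falling); and $\sigma(t)$ is the fraction of the
cohort that survives S, G2 and M, the product of
$\exp(-\int d_{phase})$ over the absolute-time window the cohort spent in
each phase.  The S window of the cohort dividing at $t$ is
$[t - T(t),\, t - T(t) + T_S]$, the G2 window runs to $t - T_M$, and the M
window to $t$; $T_{G2}$ is evaluated at the division time.  The model is
linear, so the initial population size only sets the overall scale; the
relevant outputs are phase fractions, growth rates and response ratios.

`entry_time()` ($t \mapsto t - T(t)$) is strictly increasing whenever
$|T'(t)| < 1$; the preset constructor rejects parameter combinations that
violate this (cohorts would otherwise overtake each other and the flux
formulation would break).

## Numerical scheme

`simulate_population()` integrates the single delayed scalar equation by
the method of steps with fixed-step RK4 (default $dt = 0.01$ h, bounded
above by 0.05 h and by a quarter of the shortest phase).  The delayed flux
is read from the stored grid through a 4-point cubic Lagrange stencil; the
delay always exceeds the step by orders of magnitude, so the stencil never
touches the moving front.  All time-dependent coefficients, including
$\sigma(t)$, are state-independent and precomputed vectorized in R; the
inner loop is a small compiled kernel.  The history for $t < 0$ is a
constant state (all cells in G0/G1); reported quantities discard the first
72 h, after which the population has locked onto the clock and the history
choice is immaterial.  Step-halving changes late totals by well under
0.1%, and identical inputs reproduce trajectories bit-for-bit.

The S, G2 and M compartments are not integrated as separate delay
equations: they are reconstructed after the fact as survival-weighted
integrals of the stored S-entry flux over each phase's residence window
(cumulative trapezoids on the simulation grid).  This is equivalent by
construction and conserves cells exactly at the discretization level.

Drug-induced death rates are truncated-Gaussian pulses (peak $k_{max}$,
spread $w$, support $\pm 2.5 w$); all hazard integrals, including the
cumulative hazards used in the compartment reconstruction, are closed
forms in the Gaussian CDF, so survival fractions carry no quadrature
error.  The one-day averages of the analytic treatment theory are computed
by composite Simpson on a fixed fine grid (16384 panels): the integrands
are smooth except for kinks where a phase window crosses a pulse
truncation edge, and a fine fixed grid is both robust to those kinks and
deterministic.  Agreement with $10^5$-point Riemann references is at the
$10^{-10}$ level.

## Parameters and presets

| parameter | meaning | host | fast tumor | slow tumor |
|---|---|---|---|---|
| $\bar\kappa$ (1/h) | mean G1--S rate | 0.0461 | 0.0446 | 0.0532 |
| $a_\kappa$ | G1--S modulation | 0.248 | 0.405 | 0.344 |
| $t_\kappa$ (h) | G1--S peak time | 9.42 | 3.0 | 8.0 |
| $T_S$ (h) | S duration | 9 | 8 | 20 |
| $\bar T_{G2}$, $T_M$ (h) | G2, M durations | 3, 1 | 3, 1 | 3, 1 |
| $a_{G2}$, $t_{G2}$ | G2 modulation | 0.1, 14 | 0.05, 14 | 0.05, 14 |
| $\gamma$ (1/h) | permanent G1 loss | 0.01 | 0.01 | 0.01 |
| $d_S, d_{G2}, d_M$ (1/h) | basal apoptosis | 0.001 | 0.001 | 0.001 |

The kinetic literature for bone-marrow progenitors and colorectal tumors
fixes the durations ($T_S \approx 9$ h for marrow; short versus long
S phases separating fast from slow tumors, with colorectal cell cycles
ranging from tens to over a hundred hours) but not the gating parameters.
Those were calibrated with `calibrate_preset()` (deterministic
Nelder-Mead, fixed start) against the daily S-phase fraction windows of
the three reference tissues: host 20--30% peaking at 12:00, fast tumor
15--30%, slow tumor 42--47%.  The host fit pins $(\bar\kappa, a_\kappa,
t_\kappa)$; the tumor fraction ranges pin $(\bar\kappa, a_\kappa)$ but
leave the tumor clock phases free, and these were fixed once against the
reported best S-drug administration times for the two tumor classes
(02:00 fast, 22:00 slow).  Calibration residuals on the fraction targets
are below $10^{-6}$; a preset that already meets its targets is returned
unchanged, making recalibration idempotent.  `circadian_input()` carries
the reference circadian signal $C(t) = 1 + 0.2\cos(2\pi(t - 14)/24)$.

The default schedule is the standard chronomodulated course: five
administrations at 24 h intervals, pulses of spread 2.3 h truncated at
$\pm2.5$ spreads (an 11.5 h support, the typical clinical chronomodulated
fluoropyrimidine profile), $k_{max} = 0.3$/h, first administration on
day 4 so that transients have died out.  `flat_equivalent_rate()` gives
the constant infusion delivering the same one-day integrated hazard.

## Scoring treatment schedules

`response()` is the treated-to-untreated total cell ratio seven days
after the first administration.  `scan_treatment_time()` scores a
host--tumor pair over all administration clock times.  Its default score
min--max scales the two response curves over the scan before
differencing.  The pointwise difference $R_H - R_C$ (available as
`form = "difference"`, and the form `outcome_score()` implements) is the
small-perturbation limit of any score that rewards host tolerance and
penalizes tumor survival; but at course-level kill depths a deeply killed
population's response curve is compressed toward zero, and its timing
signal disappears from the raw difference — the score degenerates to host
tolerance alone.  The slow tumor here keeps ~44% of its cells in S phase
and is killed roughly five times deeper than the host, so only the scaled
form recovers a genuine tolerance-versus-efficacy trade-off; it is also
the normalization the reference analyses of non-24 h schedules use.  A
log-ratio form is available as well.

## The analytic timing theory

For a 24 h-periodic hazard the circadian contribution to the growth rate
is, to first order, the one-day correlation of two zero-mean oscillations:

$$I(t_0) = \frac{1}{24}\int_0^{24} \tilde s(t;\,t_0)\,
\tilde\kappa\big(t - T(t)\big)\,dt,$$

with $\tilde s$ the oscillatory part of the per-division survival under
the daily hazard positioned at $t_0$, and $\tilde\kappa$ evaluated at the
cohort's S-entry time — the entry-time argument is what makes the
closed-form extrema come out at the S-entry peak plus half the window,
and it is validated against the numerically located extrema.  Because
$t_0$ shifts the hazard rigidly, $I(t_0)$ carries only the fundamental
harmonic: its extrema are exactly 12 h apart.

For an S-phase drug the cohort hit hardest is the one whose S window is
centered on the pulse, so the maximal kill occurs at
$t_0 = t_\kappa + T_S/2$ and the maximal sparing 12 h later
(`s_phase_extrema()`).  At $T_S = 24$ h every cohort accumulates the same
daily hazard and timing has no effect.  Beyond 24 h every cohort is hit
at least once per day and only the second hit differentiates them: the
extrema coincide with those of the $T_S - 24$ case, i.e. they sit 12 h
off the naive continuation of the sub-24 h rule.  The peak-to-trough
amplitude of $I$ as a function of $T_S$ (`outcome_amplitude()`) is
evaluated in the linearized-survival (small-kill) limit where the theory's
closed forms live; there it is exactly symmetric about $T_S = 12$ on
$(0, 24)$, because the first Fourier coefficient of a window indicator
and of its complement have equal magnitude.

G2/M-targeted drugs use the same integral with the hazard windows over
the G2+M transit, located numerically.  A G1-targeted drug does not act
through the division-survival factor; its drag on the growth rate is the
death rate weighted by the *G1 share of the population*, so
`g1_growth_contribution()` correlates the daily hazard with the periodic
untreated G1 fraction (simulated once, folded onto clock time).  Using
the G1 cell count instead of its share misplaces the extrema by many
hours when the total population itself oscillates strongly — this was
checked explicitly against full simulations.

`tato_outcome_extrema()` assembles the analytic analogue of the simulated
score: per-population predicted growth rates (mean daily hazard plus
$I(t_0)$, pushed through the characteristic equation
$\lambda = -(\bar\kappa + \gamma) + 2\bar\sigma\bar\kappa e^{-\lambda
\bar T}$), converted to predicted responses over the course and scored
like the simulation scan.  Across the six target-phase-by-tumor cases the
analytic best times land within about 2 h of the full simulations.

## Non-24 h schedules and the clock-free limit

With $n$ administrations at interval $T$ near 24 h, the administration
clock times drift by $T - 24$ per day and the course behaves like a 24 h
course at the mean phase; matching a target phase requires advancing the
start by $(n-1)(T-24)/2$ — 2 h per interval hour for $n = 5$
(`equivalent_start_time()`).  At $T = 24(1 \mp 1/n)$ the $n$ phases
spread uniformly over the day and the outcome loses its start-time
dependence (`uniform_phase_intervals()`; 19.2 h and 28.8 h for $n = 5$).
Both effects are visible in `scan_interval_vs_start()`: the outcome
amplitude over start time is largest (and the global best and worst
outcomes occur) at 24 h, with sharp minima at the uniform-phase
intervals.

Ignoring the clock altogether, `clock_free_min_sensitive_time()` analyses
resonance scheduling: an administration that empties the sensitive phase
is best repeated when the refilled sensitive *fraction* is again minimal.
In the reduced model used for this closed form — exponential G0/G1 with
rate $\bar\kappa$, sensitive transit $T_S$, instantaneous G2/M with
doubling on exit — the post-kill fraction rises, then dips as the first
surviving progeny double the denominator, and the dip satisfies
$e^{-\kappa s} + 2\kappa s = 2 - e^{-\kappa T_S}$ at $s = t^* - T_S$,
solved by the principal branch of the Lambert W function.  The package
cross-checks the W form against direct minimization and against an
independent Euler integration of the toy model.  Intervals at or below
$T_S$ kill every cohort outright: no cell can traverse the sensitive
phase between administrations.

## What the simulations do and do not show

All experiments here are simulations of a deliberately minimal model.
The generator emulates: daily phase-fraction rhythms matching the
reported tissue windows, exponential growth with circadian modulation,
course-level responses to phase-specific kill, and the dependence of
best/worst administration times on S-phase duration and growth rate.  It
does not emulate pharmacokinetics or drug metabolism (the killing rate
*is* the exposure), cell-cycle-length heterogeneity beyond the
exponential G1, inter-patient chronotype variation, nonlinear homeostatic
feedback between courses, or acquired resistance.  Passing tests
therefore certify the model's internal consistency and its agreement with
the reported simulation-level results — not clinical dosing advice.

Two reported quantities resist this parameter family and are knowingly
left imperfect: the worst fast-tumor S-drug time (the model yields
~15:50 against a reported 17:30; the best-worst gap saturates near 14 h
here for every kill rate and pulse width probed) and the maximal
fast-versus-slow spread of best times (8.5 h against a reported 9 h,
within the 0.5 h scan resolution).  Both depend on the calibrated presets
standing in for kinetic values that are not published; the analytic
results (12 h separations and shifts, uniform-phase intervals, the 2 h/h
start-time advance, the Lambert-W optimum) are parameter-free.

## Problem sizes

Default runs integrate 264 h at $dt = 0.01$ h (a few tens of
milliseconds each).  The shipped scans use a 0.5 h start-time grid
(instrument resolution of the reported times; extrema are refined by
quadratic interpolation), a 0.25 h grid for the analytic curves, 1 h
duration steps for the duration scan and 0.4 h steps over 16--32 h for
the interval scan.  Calibration simulates 144 h at $dt = 0.02$ h per
objective evaluation.
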