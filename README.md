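# chronocycle

Cell-cycle phase-specific (CCS) cytotoxic drugs — 5-FU and cisplatin in
S phase, docetaxel in M, seliciclib in G1 — kill only the cells that
happen to be in their target phase, and the circadian clock gates when
cells are there.  `chronocycle` is an R package for asking *when, over the
day, such a drug should be given*: it simulates host (bone-marrow-like)
and tumor cell populations whose cell cycle is circadian-gated, scores
chronomodulated infusion schedules by a tolerance-versus-efficacy
trade-off, and provides an analytic theory that predicts the best and
worst administration times directly from cell-cycle kinetics, without
running the simulations.

## Model

A linear population model with four compartments.  G0/G1 empties into
S phase at a clock-gated rate
κ(t) = κ̄[1 + a<sub>κ</sub> cos(2π(t − t<sub>κ</sub>)/24)]; S, G2 and M
are deterministic transit phases (the G2 duration is itself 24 h
periodic); cells divide in two at the end of M.  Everything closes on a
single delayed balance equation for G0/G1,

```
dN_G1/dt = −(κ(t) + γ + d_drug(t))·N_G1(t) + 2·(1 − T′(t))·σ(t)·F(t − T(t)),
```

with F = κ·N_G1 the S-entry flux, T(t) the S+G2+M transit of the cohort
dividing at t, and σ(t) that cohort's survival of the phase-specific
death rates (basal apoptosis plus the drug's truncated-Gaussian infusion
pulses).  Treatment schedules are scored by the responses
R = N<sub>treated</sub>/N<sub>untreated</sub> of host and tumor seven
days after the first administration.

The analytic theory (period-averaged perturbation analysis) reduces the
timing question to a one-day correlation integral
I(t₀) = (1/24)∫ s̃(t; t₀)·κ̃(t − T(t)) dt between the oscillatory
survival and the oscillatory G1→S rate.  Its closed forms: an S-phase
drug kills most when given half an S-phase after the daily G1→S peak
(t₀ = t<sub>κ</sub> + T_S/2) and spares most 12 h later; n
administrations at interval T near 24 h behave like a 24 h course whose
phase is met by advancing the start (n−1)(T−24)/2 hours; intervals
24(1 ± 1/n) spread the doses uniformly over the day and erase the timing
effect; and in the clock-free limit the resonance-optimal re-dosing time
satisfies a Lambert-W identity.

## Worked example

```r
library(chronocycle)
host <- shipped_preset("host")        # calibrated bone-marrow kinetics
tr   <- simulate_population(host, t_end = 120, dt = 0.02)
fr   <- phase_fractions(tr)
post <- fr[fr$time >= 72, ]           # discard the 72 h transient
sprintf("S fraction over the day: %.1f%%-%.1f%%, peak at %.1f h",
        100 * min(post$frac_s), 100 * max(post$frac_s),
        clock_time(post$time[which.max(post$frac_s)]))
#> "S fraction over the day: 20.0%-30.0%, peak at 12.0 h"
```

The host's S-phase fraction oscillates between 20% and 30% and peaks at
noon — the daily window a well-timed S-phase drug exploits.  Scanning a
standard course (5 chronomodulated administrations, 24 h apart) against
a fast-growing tumor:

```r
fast <- shipped_preset("tumor_fast")
scan_treatment_time(host, fast, sched_template = schedule(), dt = 0.02)
#> <time_scan> S drug, host 'host' vs tumor 'tumor_fast', 0.5 h grid
#>   best start 02.50 h (refined 02.30), worst 16.00 h (refined 15.82)
```

The best time to treat this tumor is around 02:00 at night (the tumor's
S-phase cells are exposed while the host marrow is spared); a few hours
past midday is the worst.  The analytic prediction for the tumor alone,
no simulation required:

```r
phase_extrema("S", fast)
#> <tato_prediction> S drug (closed_form): max kill 07.00 h, max sparing 19.00 h
#>   perturbation amplitude 0.007753 /h
```

and two schedule-design quantities:

```r
clock_free_min_sensitive_time(8, 0.05)  # resonance re-dosing optimum (h)
#> [1] 13.82262
uniform_phase_intervals(5)              # timing-insensitive intervals (h)
#> [1] 19.2 28.8
```

`best_worst_table()` assembles the full simulation-versus-theory
comparison over the three drug target phases and both tumor classes;
`scan_duration_vs_time()` and `scan_interval_vs_start()` reproduce the
response landscapes over S-phase duration and administration interval.
A thin command-line front end (`exec/chronocycle`) exposes `simulate`,
`scan-time`, `scan-duration`, `scan-interval`, `table`, `tato` and
`calibrate` subcommands over YAML preset/schedule files.

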