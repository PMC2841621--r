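## Period-averaged theoretical analysis of treatment outcome.
##
## For a 24 h-periodic treatment, the circadian contribution to the
## population growth rate is approximated by the one-day average of the
## product of two zero-mean oscillations: the per-division survival
## fraction of the cohort dividing at t, and the G1-S transition rate at
## that cohort's S-entry time,
##     I(t0) = (1/24) * int_0^24 s~(t; t0) * kappa~(t - T(t)) dt.
## A positive I speeds the population up relative to the mean-hazard
## prediction; a negative I slows it down.  The administration time t0
## shifts the daily hazard pattern rigidly, so I(t0) carries only the
## fundamental circadian harmonic and its extrema are 12 h apart.

# one-day periodic death profile of a schedule (course effects ignored)
daily_profile <- function(preset, sched, start_time = sched$start_time) {
  structure(list(base = c(g1 = 0, s = preset$death_s, g2 = preset$death_g2,
                          m = preset$death_m),
                 drug = hazard_daily(start_time, sched$k_max,
                                     sched$infusion_width, sched$cutoff),
                 target = sched$target_phase),
            class = "death_rate_profile")
}

# oscillatory part of the G1-S transition rate
kappa_tilde <- function(t, preset, circ = circadian_input()) {
  preset$kappa_mean * preset$kappa_mod_amp *
    cos(2 * pi * (t - preset$kappa_mod_phase) / circ$period)
}

# one-day average of a vectorized integrand by composite Simpson on a
# fine fixed grid.  The integrands here are smooth except for kinks where
# a phase window crosses a pulse-truncation edge; a fixed fine grid is
# robust to those kinks and keeps every period average deterministic.
day_average <- function(f, n = 16384L) {
  t <- seq(0, 24, length.out = n + 1L)
  y <- f(t)
  w <- rep(c(4, 2), length.out = n - 1L)
  sum(y[1], w * y[2:n], y[n + 1L]) * (24 / n) / 3 / 24
}

#' Periodic growth-rate contribution of a 24 h-interval treatment
#'
#' The one-day average of the product between the zero-mean part of the
#' per-division survival fraction (under the schedule's daily hazard,
#' positioned at `start_time`) and the zero-mean part of the G1-S
#' transition rate evaluated at the cohort's S-phase entry.  Computed by
#' adaptive quadrature.  Supports `S` and `G2M` target phases (a
#' G1-targeted drug does not act through the division-survival factor; see
#' [phase_extrema()]).
#'
#' @param preset a [cell_cycle_preset()].
#' @param circ a [circadian_input()].
#' @param sched a [schedule()] with `interval = 24`.
#' @param start_time administration clock time in hours (defaults to the
#'   schedule's).
#' @return the contribution `I(start_time)` (1/h, dimension of a rate
#'   because `kappa~` carries 1/h).
#' @export
periodic_growth_contribution <- function(preset, circ = circadian_input(),
                                         sched,
                                         start_time = sched$start_time) {
  if (sched$target_phase == "G1")
    stop("use phase_extrema() for G1-targeted drugs")
  prof <- daily_profile(preset, sched, start_time)
  s_day <- function(t) stage_survival(t, preset, prof, circ)
  sbar <- day_average(s_day)
  day_average(function(t) {
    te <- t - sgm_total_delay(t, preset, circ)
    (s_day(t) - sbar) * kappa_tilde(te, preset, circ)
  })
}

# I(t0) on a grid of start times (shared survival-shape trick: shifting t0
# shifts the survival pattern rigidly, so evaluate once and roll)
growth_contribution_curve <- function(preset, circ, sched, starts) {
  vapply(starts, function(s0)
    periodic_growth_contribution(preset, circ, sched, s0), numeric(1))
}

#' TATO prediction container
#'
#' @param target_phase `"G1"`, `"S"` or `"G2M"`.
#' @param best_time clock time (h) of maximal cell kill -- the best
#'   administration time when the population is the treatment target.
#' @param worst_time clock time (h) of maximal sparing (minimal kill).
#' @param amplitude peak-to-trough amplitude of the perturbation integral
#'   over the administration time (1/h), `NA` if not evaluated.
#' @param method `"closed_form"` or `"numeric"`.
#' @param degenerate `TRUE` when the timing has no effect (flat integral).
#' @return an object of class `tato_prediction`.
#' @export
tato_prediction <- function(target_phase, best_time, worst_time,
                            amplitude = NA_real_, method = "numeric",
                            degenerate = FALSE) {
  structure(list(target_phase = target_phase,
                 best_time = if (degenerate) NA_real_ else
                   clock_time(best_time),
                 worst_time = if (degenerate) NA_real_ else
                   clock_time(worst_time),
                 amplitude = amplitude, method = method,
                 degenerate = degenerate),
            class = "tato_prediction")
}

#' @export
print.tato_prediction <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<tato_prediction> %s drug: timing has no effect (degenerate)\n",
                x$target_phase))
  } else {
    cat(sprintf("<tato_prediction> %s drug (%s): max kill %05.2f h, max sparing %05.2f h\n",
                x$target_phase, x$method, x$best_time, x$worst_time))
    if (!is.na(x$amplitude))
      cat(sprintf("  perturbation amplitude %.4g /h\n", x$amplitude))
  }
  invisible(x)
}

#' @export
as.list.tato_prediction <- function(x, ...) unclass(x)

#' Closed-form extrema for an S-phase drug
#'
#' For sinusoidal circadian gating and a daily S-phase drug, the cohort
#' killed hardest is the one whose S-phase window is centered on the
#' administration; the largest kill therefore occurs when the drug is given
#' half an S-phase duration after the daily G1-S transition peak, and the
#' largest sparing 12 h later:
#' \deqn{t_{kill} = t_\kappa + T_S/2, \qquad t_{spare} = t_{kill} + 12
#'  \pmod{24}.}
#' When `ts` exceeds 24 h every cohort is hit at least once per day and
#' only the second daily hit differentiates cohorts, which shifts both
#' extrema by a further 12 h; at `ts = 24` h all cohorts accumulate the
#' same hazard and the timing has no effect (degenerate).
#'
#' @param t_kappa clock time of the daily G1-S transition-rate peak (h).
#' @param ts S phase duration (h).
#' @return a [tato_prediction()] (`best_time` = max kill).
#' @export
s_phase_extrema <- function(t_kappa, ts) {
  stopifnot(ts > 0)
  if (isTRUE(all.equal(ts %% 24, 0)))
    return(tato_prediction("S", NA, NA, amplitude = 0,
                           method = "closed_form", degenerate = TRUE))
  kill <- t_kappa + ts / 2 + if (ts > 24) 12 else 0
  tato_prediction("S", kill, kill + 12, method = "closed_form")
}

# numeric extrema of a perturbation-integral curve over start time
numeric_extrema <- function(fun, grid_step = 0.25, tol_flat = 1e-10) {
  starts <- seq(0, 24 - grid_step, by = grid_step)
  vals <- vapply(starts, fun, numeric(1))
  amp <- max(vals) - min(vals)
  if (amp < tol_flat)
    return(list(degenerate = TRUE, amplitude = amp))
  ref <- function(idx, maximum) {
    lo <- starts[idx] - grid_step
    hi <- starts[idx] + grid_step
    optimize(function(x) fun(clock_time(x)), c(lo, hi),
             maximum = maximum, tol = 1e-6)[[1]]
  }
  list(degenerate = FALSE, amplitude = amp,
       t_max = clock_time(ref(which.max(vals), TRUE)),
       t_min = clock_time(ref(which.min(vals), FALSE)),
       starts = starts, values = vals)
}

#' TATO extrema for any target phase
#'
#' Best (maximal-kill) and worst (maximal-sparing) administration clock
#' times predicted by the period-averaged analysis for one population.
#' For an S-phase drug the closed-form rule [s_phase_extrema()] is used
#' (with a numeric amplitude); for a G2/M drug the extrema are located
#' numerically from [periodic_growth_contribution()] with the hazard over
#' the G2+M transit; for a G1 drug the perturbation integral couples the
#' chronomodulated G1 death rate to the periodic G1 population share of
#' the untreated solution, evaluated numerically on a simulated day.
#'
#' @param target_phase `"G1"`, `"S"` or `"G2M"`.
#' @param preset a [cell_cycle_preset()].
#' @param circ a [circadian_input()].
#' @param sched a [schedule()] (its target phase is overridden).
#' @param grid_step start-time grid for the numeric search (h).
#' @param g1_wave optional precomputed [g1_daily_profile()] (recomputed if
#'   `NULL` and needed).
#' @return a [tato_prediction()] (`best_time` = max kill).
#' @export
phase_extrema <- function(target_phase = c("S", "G1", "G2M"), preset,
                          circ = circadian_input(), sched = schedule(),
                          grid_step = 0.25, g1_wave = NULL) {
  target_phase <- match.arg(target_phase)
  sched$target_phase <- target_phase
  if (preset$kappa_mod_amp == 0 && preset$g2_mod_amp == 0)
    return(tato_prediction(target_phase, NA, NA, amplitude = 0,
                           method = "numeric", degenerate = TRUE))
  if (target_phase == "S") {
    pred <- s_phase_extrema(preset$kappa_mod_phase, preset$ts)
    if (!pred$degenerate) {
      vals <- growth_contribution_curve(preset, circ, sched,
                                        seq(0, 23, by = 1))
      pred$amplitude <- max(vals) - min(vals)
    }
    return(pred)
  }
  if (target_phase == "G2M") {
    fun <- function(s0) periodic_growth_contribution(preset, circ, sched,
                                                     s0)
  } else {
    wave <- if (is.null(g1_wave)) g1_daily_profile(preset, circ) else
      g1_wave
    fun <- function(s0) g1_growth_contribution(preset, circ, sched, s0,
                                               wave)
  }
  ex <- numeric_extrema(fun, grid_step)
  if (ex$degenerate)
    return(tato_prediction(target_phase, NA, NA, amplitude = ex$amplitude,
                           method = "numeric", degenerate = TRUE))
  # max growth = max sparing; min growth = max kill
  tato_prediction(target_phase, best_time = ex$t_min,
                  worst_time = ex$t_max, amplitude = ex$amplitude,
                  method = "numeric")
}

#' Daily G0/G1 occupancy profile of the untreated population
#'
#' Simulates the untreated clock-gated population and folds the
#' post-transient G0/G1 *fraction of the total* onto clock time.  The
#' fraction (not the raw G1 cell number) is the right weight for a
#' G1-targeted drug: the drug's drag on the population growth rate is the
#' death rate times the G1 share of the population, and both the G1 count
#' and the total oscillate.  Used by the G1-drug perturbation integral.
#'
#' @param preset a [cell_cycle_preset()].
#' @param circ a [circadian_input()].
#' @param dt integration step (h).
#' @return a function of clock time returning the periodic G1 fraction.
#' @export
g1_daily_profile <- function(preset, circ = circadian_input(), dt = 0.02) {
  tr <- simulate_population(preset, circ, NULL, t_end = 144, dt = dt)
  sel <- tr$times >= 96
  w <- (tr$states$n_g1 / rowSums(tr$states))[sel]
  ct <- clock_time(tr$times[sel])
  grid <- seq(0, 24 - 0.05, by = 0.05)
  idx <- floor(ct / 0.05) %% length(grid) + 1
  prof <- as.numeric(tapply(w, factor(idx, levels = seq_along(grid)),
                            mean))
  gx <- c(grid, 24)
  gy <- c(prof, prof[1])
  function(tc) approx(gx, gy, xout = clock_time(tc))$y
}

#' Perturbation integral for a G1-targeted drug
#'
#' A G1-targeted drug drags the population growth rate by its death rate
#' times the G1 share of the population, so the circadian contribution is
#' `-(1/24) * int_0^24 d~(t; t0) * w~(t) dt`, with `d~` the zero-mean part
#' of the daily drug hazard and `w~` the zero-mean part of the untreated
#' periodic G1 fraction.
#'
#' @inheritParams phase_extrema
#' @param start_time administration clock time (h).
#' @param g1_wave a [g1_daily_profile()] function.
#' @return the contribution (1/h).
#' @export
g1_growth_contribution <- function(preset, circ = circadian_input(), sched,
                                   start_time, g1_wave) {
  h <- hazard_daily(start_time, sched$k_max, sched$infusion_width,
                    sched$cutoff)
  dbar <- flat_equivalent_rate(sched)
  wbar <- day_average(g1_wave)
  day_average(function(t) -(hazard_rate(h, t) - dbar) * (g1_wave(t) - wbar))
}

#' Amplitude of the timing effect versus S-phase duration
#'
#' Peak-to-trough amplitude of the perturbation integral over the
#' administration time, for an S-phase drug and sinusoidal gating, as a
#' function of the S-phase duration.  Evaluated in the small-kill
#' (linearized-survival) limit in which the analysis' closed forms live:
#' the survival oscillation is replaced by the (negative, zero-mean)
#' oscillation of the accumulated hazard, making the amplitude an exactly
#' symmetric function of `ts` about 12 h on (0, 24) and zero at `ts = 24`
#' (every cohort then collects the same daily hazard and the timing has no
#' effect).
#'
#' @param ts S phase duration in hours.
#' @param circ a [circadian_input()].
#' @param preset a [cell_cycle_preset()] supplying the gating parameters.
#' @param sched a [schedule()] supplying the pulse shape.
#' @return the peak-to-trough amplitude (1/h).
#' @export
outcome_amplitude <- function(ts, circ = circadian_input(),
                              preset = cell_cycle_preset(
                                kappa_mean = 0.05, kappa_mod_amp = 0.3,
                                kappa_mod_phase = 14),
                              sched = schedule()) {
  preset$ts <- ts
  prof <- daily_profile(preset, sched, 0)
  # linearized survival oscillation: -(accumulated drug hazard - mean)
  o_fun <- function(t) {
    te <- t - sgm_total_delay(t, preset, circ)
    hazard_integral(prof$drug, te, te + ts)
  }
  obar <- day_average(o_fun)
  I_lin <- function(t0) {
    day_average(function(t) {
      te <- t - sgm_total_delay(t, preset, circ)
      -(o_fun(clock_time(t - t0)) - obar) * kappa_tilde(te, preset, circ)
    })
  }
  ex <- numeric_extrema(I_lin, grid_step = 1)
  if (ex$degenerate) 0 else ex$amplitude
}

#' Equivalent starting time for non-24 h intervals
#'
#' For a course of `n_admin` administrations at an interval `T` close to
#' 24 h, the clock times of the administrations drift by `T - 24` per day;
#' the course is equivalent to a 24 h-interval course at the mean clock
#' phase.  To realize a target phase `t_star` the first administration must
#' be advanced:
#' \deqn{t_0 = t_\star - (n-1)\,(T-24)/2 \pmod{24}.}
#' With 5 administrations, each hour of interval increment advances the
#' start by 2 h.
#'
#' @param interval administration interval `T` in hours.
#' @param n_admin number of administrations.
#' @param t_star target mean clock phase (h).
#' @return starting clock time in `[0, 24)`, with attribute `valid` --
#'   `FALSE` when `|interval - 24| >= 24/n_admin`, where the
#'   administrations spread over the whole day and the mean phase loses
#'   its meaning.
#' @export
equivalent_start_time <- function(interval, n_admin, t_star) {
  stopifnot(n_admin >= 1, interval > 0)
  t0 <- clock_time(t_star - (n_admin - 1) * (interval - 24) / 2)
  structure(t0, valid = abs(interval - 24) < 24 / n_admin)
}

#' Intervals that spread administrations uniformly over the day
#'
#' The two intervals flanking 24 h at which the `n` administration clock
#' times of one course are equispaced over the circadian cycle (gap
#' `24/n`), making the outcome insensitive to the first-day start time:
#' `24 * (1 -+ 1/n)`.
#'
#' @param n_admin number of administrations (>= 2).
#' @return numeric vector `c(short, long)` in hours.
#' @export
uniform_phase_intervals <- function(n_admin) {
  stopifnot(n_admin >= 2)
  c(24 * (1 - 1 / n_admin), 24 * (1 + 1 / n_admin))
}

## ---- clock-free resonance analysis --------------------------------------

# closed-form sensitive fraction after a total S-phase kill in the
# clock-free toy model (instantaneous G2/M, no basal death):
# for elapsed time t in (ts, 2 ts), with y = kappa * (t - ts) and
# b = exp(-kappa ts),
#   f(t) = [2 - exp(-y) (1 + 2 y + b)] / (2 - exp(-y))
clockfree_sensitive_fraction <- function(t, ts, kappa) {
  b <- exp(-kappa * ts)
  ifelse(t <= ts,
         (1 - exp(-kappa * t)),  # S refilling, no divisions yet
         {
           y <- kappa * (t - ts)
           (2 - exp(-y) * (1 + 2 * y + b)) / (2 - exp(-y))
         })
}

#' Post-administration time of minimal sensitive fraction (clock-free)
#'
#' In the clock-free limit, an administration that kills every cell in the
#' sensitive (S) phase empties that compartment; it refills from G0/G1,
#' overshoots, and -- once the surviving cells' progeny start dividing --
#' dips to a local minimum before settling back.  Administering the next
#' dose at that minimum spares the most cells.  In the reduced model
#' (exponential G1 with rate `kappa_mean`, S transit `ts`, instantaneous
#' G2/M, division factor 2) the minimum lies at `t* = ts + s*` where `s*`
#' solves the stationarity condition
#' \deqn{e^{-\kappa s} + 2 \kappa s = 2 - e^{-\kappa T_S},}
#' whose solution is, via the principal branch of the Lambert W function
#' (with `c = 2 - exp(-kappa ts)`):
#' \deqn{\kappa s^* = c/2 + W_0\!\left(-\tfrac{1}{2} e^{-c/2}\right).}
#'
#' @param ts sensitive-phase (S) duration in hours.
#' @param kappa_mean mean G1-S transition rate (1/h).
#' @return the elapsed time `t*` (hours) after the administration at which
#'   the sensitive fraction is minimal, with attributes `residual` (the
#'   stationarity-identity residual) and `s_star`.
#' @export
clock_free_min_sensitive_time <- function(ts, kappa_mean) {
  stopifnot(ts > 0, kappa_mean > 0)
  cc <- 2 - exp(-kappa_mean * ts)
  y <- cc / 2 + pracma::lambertWp(-exp(-cc / 2) / 2)
  if (!is.finite(y) || y <= 0 || y >= kappa_mean * ts)
    stop("no interior minimum in the first refill cycle (degenerate ",
         "parameters)")
  s_star <- y / kappa_mean
  residual <- exp(-y) + 2 * y - cc
  structure(ts + s_star, residual = residual, s_star = s_star)
}
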