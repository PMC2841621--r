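#' Clock-gated G1-S transition rate
#'
#' \deqn{\kappa(t) = \bar\kappa\,[1 + a_\kappa\cos(2\pi(t - t_\kappa)/24)]}
#' 24 h periodic, with mean `kappa_mean` and daily peak at clock time
#' `kappa_mod_phase`.
#'
#' @param t time in hours (vectorized).
#' @param preset a [cell_cycle_preset()].
#' @param circ a [circadian_input()]; supplies the period.
#' @return transition rate in 1/h.
#' @export
g1s_transition_rate <- function(t, preset, circ = circadian_input()) {
  preset$kappa_mean *
    (1 + preset$kappa_mod_amp *
       cos(2 * pi * (t - preset$kappa_mod_phase) / circ$period))
}

#' Clock-dependent G2 phase duration
#'
#' \deqn{T_{G2}(t) = \bar T_{G2}\,[1 + a_{G2}\cos(2\pi(t - t_{G2})/24)]}
#'
#' @inheritParams g1s_transition_rate
#' @return G2 duration in hours (always > 0 for a valid preset).
#' @export
g2_duration <- function(t, preset, circ = circadian_input()) {
  preset$tg2_mean *
    (1 + preset$g2_mod_amp *
       cos(2 * pi * (t - preset$g2_mod_phase) / circ$period))
}

# d/dt of the total S+G2+M transit time (only the G2 term varies)
sgm_delay_slope <- function(t_div, preset, circ = circadian_input()) {
  w <- 2 * pi / circ$period
  -preset$tg2_mean * preset$g2_mod_amp * w *
    sin(w * (t_div - preset$g2_mod_phase))
}

#' Total S+G2+M transit time of the cohort dividing at a given time
#'
#' `T(t_div) = ts + T_G2(t_div) + tm`: the S, G2 and M transit attributed to
#' the cohort that divides at `t_div` (the clock-dependent G2 duration is
#' evaluated at the division time).
#'
#' @param t_div division time in hours (vectorized).
#' @inheritParams g1s_transition_rate
#' @return transit time in hours.
#' @export
sgm_total_delay <- function(t_div, preset, circ = circadian_input()) {
  preset$ts + g2_duration(t_div, preset, circ) + preset$tm
}

#' S-entry time of the cohort dividing at a given time
#'
#' Maps a division time to the time the same cohort entered S phase,
#' `t_entry = t_div - T(t_div)`.  Under the delay-monotonicity invariant
#' (`|dT/dt| < 1`) this map is strictly increasing, so cohorts divide in
#' the order in which they entered S.
#'
#' @param t_div division time in hours (vectorized).
#' @inheritParams g1s_transition_rate
#' @return S-entry time in hours.
#' @export
entry_time <- function(t_div, preset, circ = circadian_input()) {
  slope_max <- preset$tg2_mean * preset$g2_mod_amp * 2 * pi / circ$period
  if (slope_max >= 1)
    stop("delay monotonicity violated: |dT/dt| reaches ", signif(slope_max, 3))
  t_div - sgm_total_delay(t_div, preset, circ)
}

#' Division time of the cohort entering S phase at a given time
#'
#' Inverts [entry_time()]: solves `t_div - T(t_div) = t_entry` by Newton
#' iteration (the map is a strict order isomorphism for valid presets).
#'
#' @param t_entry S-entry time in hours (vectorized).
#' @inheritParams g1s_transition_rate
#' @param tol convergence tolerance in hours.
#' @return division time in hours.
#' @export
division_time <- function(t_entry, preset, circ = circadian_input(),
                          tol = 1e-10) {
  t_div <- t_entry + preset$ts + preset$tg2_mean + preset$tm
  for (i in 1:50) {
    f <- t_div - sgm_total_delay(t_div, preset, circ) - t_entry
    if (max(abs(f)) < tol) break
    t_div <- t_div - f / (1 - sgm_delay_slope(t_div, preset, circ))
  }
  if (max(abs(t_div - sgm_total_delay(t_div, preset, circ) - t_entry)) > 1e-6)
    stop("division_time failed to converge; check delay monotonicity")
  t_div
}

#' Death-rate profile of a population under a schedule
#'
#' Bundles the basal per-phase apoptosis rates with the drug-induced hazard
#' of a schedule (attached to exactly one target phase: `G1`, `S` or `G2M`).
#' With `schedule = NULL` the profile is purely basal.
#'
#' @param preset a [cell_cycle_preset()].
#' @param schedule a [schedule()] or `NULL` (no treatment).
#' @return an object of class `death_rate_profile` with elements `base`
#'   (named rates for g1, s, g2, m), `drug` (a hazard descriptor) and
#'   `target` (`"none"`, `"G1"`, `"S"` or `"G2M"`).
#' @export
death_rate_profile <- function(preset, schedule = NULL) {
  base <- c(g1 = 0, s = preset$death_s, g2 = preset$death_g2,
            m = preset$death_m)
  if (is.null(schedule)) {
    drug <- hazard_none()
    target <- "none"
  } else {
    drug <- schedule_hazard(schedule)
    target <- schedule$target_phase
  }
  structure(list(base = base, drug = drug, target = target),
            class = "death_rate_profile")
}

#' Effective per-phase death rates at a time point
#'
#' Basal apoptosis rates for every phase, with the drug-induced rate of the
#' schedule added to its single target phase.  A `G1`-targeted drug adds to
#' the permanent G1 loss pathway; a `G2M`-targeted drug acts identically on
#' the G2 and M phases.
#'
#' @param t time in hours (vectorized).
#' @param preset a [cell_cycle_preset()].
#' @param schedule a [schedule()] or `NULL`.
#' @return a data.frame with columns `t`, `g1`, `s`, `g2`, `m` (rates, 1/h).
#' @export
effective_death_rates <- function(t, preset, schedule = NULL) {
  prof <- death_rate_profile(preset, schedule)
  drug <- hazard_rate(prof$drug, t)
  out <- data.frame(t = t,
                    g1 = prof$base[["g1"]] + 0 * t,
                    s = prof$base[["s"]] + 0 * t,
                    g2 = prof$base[["g2"]] + 0 * t,
                    m = prof$base[["m"]] + 0 * t)
  switch(prof$target,
         none = NULL,
         G1 = { out$g1 <- out$g1 + drug },
         S = { out$s <- out$s + drug },
         G2M = { out$g2 <- out$g2 + drug; out$m <- out$m + drug })
  out
}

# absolute-time phase windows of the cohort dividing at t_div:
#   S  : [t_e, t_e + ts]
#   G2 : [t_e + ts, t_div - tm]
#   M  : [t_div - tm, t_div]
# with t_e = t_div - T(t_div); window lengths are ts, T_G2(t_div), tm.
cohort_windows <- function(t_div, preset, circ = circadian_input()) {
  t_e <- entry_time(t_div, preset, circ)
  list(s_lo = t_e, s_hi = t_e + preset$ts,
       g2_lo = t_e + preset$ts, g2_hi = t_div - preset$tm,
       m_lo = t_div - preset$tm, m_hi = t_div,
       tg2 = g2_duration(t_div, preset, circ))
}

#' Per-division survival fraction through S, G2 and M
#'
#' The fraction of the cohort dividing at `t_div` that survives the S, G2
#' and M phases: the product of `exp(-integral of the phase death rate)`
#' over the absolute-time window the cohort spent in each phase.  Basal
#' hazards contribute `rate * duration`; the drug hazard is integrated in
#' closed form over the windows of its target phase.
#'
#' @param t_div division time in hours (vectorized).
#' @param preset a [cell_cycle_preset()].
#' @param death a [death_rate_profile()]; defaults to the basal profile.
#' @param circ a [circadian_input()].
#' @return survival fraction in `(0, 1]`.
#' @export
stage_survival <- function(t_div, preset, death = death_rate_profile(preset),
                           circ = circadian_input()) {
  w <- cohort_windows(t_div, preset, circ)
  haz <- death$base[["s"]] * preset$ts +
    death$base[["g2"]] * w$tg2 +
    death$base[["m"]] * preset$tm
  haz <- haz + switch(death$target,
    none = 0,
    G1 = 0,  # a G1 drug removes cells before S entry, not during S/G2/M
    S = hazard_integral(death$drug, w$s_lo, w$s_hi),
    G2M = hazard_integral(death$drug, w$g2_lo, w$m_hi))
  exp(-haz)
}
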