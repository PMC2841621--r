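SCHEDULE_FIELDS <- c("target_phase", "start_time", "interval", "n_admin",
                     "k_max", "infusion_width", "mode", "cutoff", "start_day")

#' Drug administration schedule
#'
#' One course of a cell-cycle phase-specific drug.  In `chrono` mode each
#' administration is a truncated-Gaussian pulse of the drug-induced death
#' rate: unit-peak Gaussian of spread `infusion_width`, cut to zero beyond
#' `cutoff` spreads, scaled by `k_max`.  Administrations are centered at
#' `start_time + j * interval` (j = 0, ..., n_admin - 1) on top of an
#' absolute-time offset of `start_day` days (the default leaves 72 h for
#' simulation transients to vanish before the course begins).  In `flat`
#' mode the same total one-day hazard is delivered at the constant
#' equivalent rate [flat_equivalent_rate()] over the whole course.
#'
#' @param target_phase phase the drug kills: `"S"`, `"G1"` or `"G2M"`.
#' @param start_time clock time of the first administration (h, `[0, 24)`).
#' @param interval hours between administrations (24 for a standard
#'   chronomodulated course).
#' @param n_admin number of administrations in the course (default 5).
#' @param k_max maximal drug-induced death rate (1/h).
#' @param infusion_width Gaussian spread of one pulse (h).  The default
#'   2.3 h, with `cutoff = 2.5`, gives a pulse spanning 11.5 h, a typical
#'   clinical chronomodulated infusion profile.
#' @param mode `"chrono"` or `"flat"`.
#' @param cutoff truncation radius in units of `infusion_width`.
#' @param start_day whole days before the first administration day.
#' @return an object of class `schedule`.
#' @export
schedule <- function(target_phase = c("S", "G1", "G2M"),
                     start_time = 0, interval = 24, n_admin = 5,
                     k_max = 0.3, infusion_width = 2.3,
                     mode = c("chrono", "flat"), cutoff = 2.5,
                     start_day = 3) {
  target_phase <- match.arg(target_phase)
  mode <- match.arg(mode)
  stopifnot(interval > 0, n_admin >= 1, k_max >= 0, infusion_width > 0,
            start_time >= 0, start_time < 24, cutoff > 0, start_day >= 0)
  structure(list(target_phase = target_phase, start_time = start_time,
                 interval = interval, n_admin = as.integer(n_admin),
                 k_max = k_max, infusion_width = infusion_width,
                 mode = mode, cutoff = cutoff,
                 start_day = as.integer(start_day)),
            class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf(paste0("<schedule> %s drug on %s: %d administrations every",
                     " %g h from %05.2f h (day %d), k_max %g /h, width %g h\n"),
              x$mode, x$target_phase, x$n_admin, x$interval, x$start_time,
              x$start_day + 1L, x$k_max, x$infusion_width))
  invisible(x)
}

#' Absolute time of the first administration
#'
#' @param sched a [schedule()].
#' @return hours since simulation start (t = 0 is midnight of day 1).
#' @export
first_admin_time <- function(sched) {
  sched$start_day * 24 + sched$start_time
}

#' Read / write schedules as YAML
#'
#' @param path a YAML file with exactly the [schedule()] field names.
#' @return `load_schedule` returns a `schedule`; `save_schedule` returns
#'   `path` invisibly.
#' @export
load_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), SCHEDULE_FIELDS)
  if (length(unknown))
    stop("unknown schedule keys: ", paste(unknown, collapse = ", "))
  do.call(schedule, y)
}

#' @rdname load_schedule
#' @param sched a [schedule()].
#' @export
save_schedule <- function(sched, path) {
  yaml::write_yaml(unclass(sched), path)
  invisible(path)
}

## ---- hazard descriptors -------------------------------------------------
## A hazard is the drug-induced death rate as a function of absolute time.
## Three shapes are supported; integrals are evaluated in closed form via
## the Gaussian CDF, so survival fractions carry no quadrature error.

hazard_none <- function() structure(list(kind = "none"), class = "drug_hazard")

hazard_pulses <- function(centers, k_max, width, cutoff) {
  structure(list(kind = "pulses", centers = centers, k_max = k_max,
                 width = width, cutoff = cutoff), class = "drug_hazard")
}

# infinite daily train of pulses at clock time `center` (+ 24k), used by
# the period-averaged analysis
hazard_daily <- function(center, k_max, width, cutoff) {
  structure(list(kind = "daily", center = center, k_max = k_max,
                 width = width, cutoff = cutoff), class = "drug_hazard")
}

hazard_flat <- function(rate, t_on, t_off) {
  structure(list(kind = "flat", rate = rate, t_on = t_on, t_off = t_off),
            class = "drug_hazard")
}

# hazard descriptor of one course
schedule_hazard <- function(sched) {
  t0 <- first_admin_time(sched)
  if (sched$k_max == 0) return(hazard_none())
  if (sched$mode == "chrono") {
    hazard_pulses(t0 + sched$interval * (seq_len(sched$n_admin) - 1L),
                  sched$k_max, sched$infusion_width, sched$cutoff)
  } else {
    hazard_flat(flat_equivalent_rate(sched), t0,
                t0 + sched$n_admin * sched$interval)
  }
}

# drug-induced death rate at time t (vectorized over t)
hazard_rate <- function(h, t) {
  switch(h$kind,
    none = rep(0, length(t)),
    flat = h$rate * (t >= h$t_on & t < h$t_off),
    pulses = {
      r <- rep(0, length(t))
      for (c in h$centers) {
        x <- (t - c) / h$width
        r <- r + h$k_max * exp(-x^2 / 2) * (abs(x) <= h$cutoff)
      }
      r
    },
    daily = {
      y <- (t - h$center) %% 24
      x1 <- y / h$width
      x2 <- (y - 24) / h$width
      h$k_max * (exp(-x1^2 / 2) * (abs(x1) <= h$cutoff) +
                 exp(-x2^2 / 2) * (abs(x2) <= h$cutoff))
    })
}

# closed-form integral of one unit-peak truncated Gaussian pulse (center c,
# spread w, truncation radius R*w) over windows [a, b]; vectorized over a, b
pulse_integral <- function(a, b, c, w, R) {
  za <- pmin(pmax((a - c) / w, -R), R)
  zb <- pmin(pmax((b - c) / w, -R), R)
  w * sqrt(2 * pi) * (pnorm(zb) - pnorm(za))
}

# integral of the hazard over windows [a, b]; vectorized over a, b
hazard_integral <- function(h, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  switch(h$kind,
    none = rep(0, length(a)),
    flat = h$rate * pmax(0, pmin(b, h$t_off) - pmax(a, h$t_on)),
    pulses = {
      s <- rep(0, length(a))
      for (c in h$centers)
        s <- s + pulse_integral(a, b, c, h$width, h$cutoff)
      h$k_max * s
    },
    daily = {
      lo <- min(a); hi <- max(b)
      R <- h$cutoff * h$width
      ks <- seq(floor((lo - h$center - R) / 24),
                ceiling((hi - h$center + R) / 24))
      s <- rep(0, length(a))
      for (k in ks)
        s <- s + pulse_integral(a, b, h$center + 24 * k, h$width, h$cutoff)
      h$k_max * s
    })
}

#' Chronomodulated drug-induced death rate
#'
#' The death-rate time course of a `chrono` schedule: the sum over the
#' administrations of a truncated-Gaussian pulse of peak `k_max`, spread
#' `infusion_width` and support `2 * cutoff * infusion_width`, centered at
#' `start_time + j * interval`.  Zero outside the support of all pulses.
#'
#' @param t absolute time in hours (vectorized).
#' @param sched a [schedule()] with `mode = "chrono"`.
#' @return drug-induced death rate in 1/h.
#' @export
chrono_death_rate <- function(t, sched) {
  stopifnot(sched$mode == "chrono")
  hazard_rate(schedule_hazard(sched), t)
}

#' Flat infusion rate with matched one-day hazard
#'
#' The constant death rate that delivers, in 24 h, the same integrated
#' hazard as one chronomodulated pulse of the schedule -- i.e. it kills the
#' same fraction of (continuously exposed) cells per day:
#' `k_flat = k_max * w * sqrt(2*pi) * (2*pnorm(cutoff) - 1) / 24`.
#'
#' @param sched a [schedule()] (its chrono pulse parameters are used).
#' @return constant rate in 1/h.
#' @export
flat_equivalent_rate <- function(sched) {
  sched$k_max * sched$infusion_width * sqrt(2 * pi) *
    (2 * pnorm(sched$cutoff) - 1) / 24
}
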