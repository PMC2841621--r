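#' Treatment response of one population
#'
#' Ratio of treated to untreated total cell number, evaluated `horizon`
#' hours (default 7 days) after the first administration.  Both runs share
#' the preset, circadian input, initial state and step size, so the ratio
#' isolates the effect of the drug; `R = 1` for a zero-dose schedule and
#' `R` decreases monotonically with the maximal killing rate.
#'
#' @param preset a [cell_cycle_preset()].
#' @param circ a [circadian_input()].
#' @param sched a [schedule()].
#' @param horizon evaluation delay after the first administration (h).
#' @param dt integration step (h).
#' @param untreated optional untreated trajectory covering the evaluation
#'   time (reused across scans); if `NULL`, it is simulated.
#' @return the response (dimensionless, in `(0, 1]` for non-negative drug
#'   rates), with attributes `n_treated`, `n_untreated`, `t_eval`.
#' @export
response <- function(preset, circ = circadian_input(), sched,
                     horizon = 168, dt = 0.01, untreated = NULL) {
  t_eval <- first_admin_time(sched) + horizon
  t_end <- t_eval + 1
  if (is.null(untreated))
    untreated <- simulate_population(preset, circ, NULL, t_end = t_end,
                                     dt = dt)
  if (max(untreated$times) < t_eval)
    stop("untreated trajectory does not cover the evaluation time")
  treated <- simulate_population(preset, circ, sched, t_end = t_end, dt = dt)
  n_un <- total_cells(untreated, t_eval)
  n_tr <- total_cells(treated, t_eval)
  if (n_un <= 0) stop("untreated total is zero at the evaluation time")
  structure(n_tr / n_un, n_treated = n_tr, n_untreated = n_un,
            t_eval = t_eval)
}

#' Treatment outcome score
#'
#' Balances host tolerance against anti-tumor efficacy:
#' `E = r_host - r_tumor` (the default difference form), or
#' `E = log(r_host / r_tumor)`.  E increases with the surviving host
#' fraction and decreases with the surviving tumor fraction; `E = 0` when
#' the two responses are equal, and swapping the arguments negates E.
#'
#' @param r_host,r_tumor responses from [response()] (must be > 0).
#' @param form `"difference"` or `"log_ratio"`.
#' @return the outcome score (dimensionless; larger is better).
#' @export
outcome_score <- function(r_host, r_tumor,
                          form = c("difference", "log_ratio")) {
  form <- match.arg(form)
  if (any(r_host <= 0) || any(r_tumor <= 0))
    stop("responses must be > 0")
  switch(form,
         difference = r_host - r_tumor,
         log_ratio = log(r_host / r_tumor))
}

# min-max scaling to [0, 1]; a constant curve maps to all zeros
minmax_scale <- function(x) {
  r <- diff(range(x))
  if (r < 1e-12) return(rep(0, length(x)))
  (x - min(x)) / r
}

# circularly contiguous plateau around an extremum: the maximal arc of
# grid points whose value is within `tol` of the extremal value and which
# contains the extremum
plateau_interval <- function(starts, value, idx, tol = 1e-3,
                             maximum = TRUE) {
  n <- length(starts)
  ok <- if (maximum) value >= value[idx] - tol else value <= value[idx] + tol
  lo <- idx
  while (ok[(lo - 2) %% n + 1] && lo > idx - n + 1) lo <- lo - 1
  hi <- idx
  while (ok[hi %% n + 1] && hi < idx + n - 1) hi <- hi + 1
  width <- (hi - lo) %% n
  list(flat = width >= n - 1,
       lo = starts[(lo - 1) %% n + 1], hi = starts[(hi - 1) %% n + 1],
       width_h = width * (starts[2] - starts[1]))
}

# quadratic (three-point) refinement of a circular grid extremum
refine_extremum <- function(starts, value, idx) {
  n <- length(starts)
  step <- starts[2] - starts[1]
  ym <- value[(idx - 2) %% n + 1]
  y0 <- value[idx]
  yp <- value[idx %% n + 1]
  den <- ym - 2 * y0 + yp
  off <- if (abs(den) < 1e-15) 0 else 0.5 * (ym - yp) / den
  clock_time(starts[idx] + pmax(-1, pmin(1, off)) * step)
}

#' Scan the treatment outcome over the administration clock time
#'
#' Runs the full host and tumor simulations for every first-administration
#' time on a grid over the day (interval fixed by the schedule template,
#' normally 24 h) and scores each schedule with [outcome_score()].  The
#' untreated reference runs are shared across the grid.
#'
#' @param host_preset,tumor_preset calibrated [cell_cycle_preset()]s.
#' @param circ a [circadian_input()].
#' @param sched_template a [schedule()]; its `start_time` is replaced by
#'   each grid value.
#' @param grid_step grid resolution in hours (must divide 24).
#' @param dt integration step (h).
#' @param form scoring of the grid.  The default `"scaled_difference"`
#'   min-max scales the host and tumor response curves over the scan
#'   before differencing, weighing toxicity and efficacy on comparable
#'   scales even when the mean kill depths differ strongly (a deeply
#'   killed tumor otherwise contributes almost no timing signal);
#'   `"difference"` and `"log_ratio"` use [outcome_score()] pointwise.
#' @param plateau_tol score tolerance used to flag plateaus around the
#'   extrema.
#' @return an object of class `time_scan`: a list with `grid` (data.frame
#'   `start_time`, `r_host`, `r_tumor`, `score`) and `summary` (best/worst
#'   start times, quadratic-refined times, plateau intervals, `flat` flag).
#' @export
scan_treatment_time <- function(host_preset, tumor_preset,
                                circ = circadian_input(), sched_template,
                                grid_step = 0.5, dt = 0.01,
                                form = c("scaled_difference", "difference",
                                         "log_ratio"),
                                plateau_tol = 1e-3) {
  form <- match.arg(form)
  if (abs(24 / grid_step - round(24 / grid_step)) > 1e-9)
    stop("grid_step must divide 24")
  starts <- seq(0, 24 - grid_step, by = grid_step)
  t_end <- first_admin_time(sched_template) + 24 + 168 + 1
  un_h <- simulate_population(host_preset, circ, NULL, t_end = t_end,
                              dt = dt)
  un_c <- simulate_population(tumor_preset, circ, NULL, t_end = t_end,
                              dt = dt)
  r_h <- r_c <- numeric(length(starts))
  for (i in seq_along(starts)) {
    s <- sched_template
    s$start_time <- starts[i]
    r_h[i] <- response(host_preset, circ, s, dt = dt, untreated = un_h)
    r_c[i] <- response(tumor_preset, circ, s, dt = dt, untreated = un_c)
  }
  score <- if (form == "scaled_difference")
    minmax_scale(r_h) - minmax_scale(r_c)
  else outcome_score(r_h, r_c, form = form)
  grid <- data.frame(start_time = starts, r_host = r_h, r_tumor = r_c,
                     score = score)
  flat <- diff(range(score)) < plateau_tol
  if (flat) {
    summary <- list(flat = TRUE, best = NA_real_, worst = NA_real_,
                    best_refined = NA_real_, worst_refined = NA_real_,
                    best_plateau = NULL, worst_plateau = NULL)
  } else {
    ib <- which.max(score)
    iw <- which.min(score)
    summary <- list(
      flat = FALSE,
      best = starts[ib], worst = starts[iw],
      best_refined = refine_extremum(starts, score, ib),
      worst_refined = refine_extremum(starts, -score, iw),
      best_plateau = plateau_interval(starts, score, ib, plateau_tol, TRUE),
      worst_plateau = plateau_interval(starts, score, iw, plateau_tol,
                                       FALSE))
  }
  structure(list(grid = grid, summary = summary,
                 metadata = list(host = host_preset$label,
                                 tumor = tumor_preset$label,
                                 target_phase = sched_template$target_phase,
                                 interval = sched_template$interval,
                                 dt = dt, grid_step = grid_step,
                                 form = form)),
            class = "time_scan")
}

#' @export
print.time_scan <- function(x, ...) {
  cat(sprintf("<time_scan> %s drug, host '%s' vs tumor '%s', %g h grid\n",
              x$metadata$target_phase, x$metadata$host, x$metadata$tumor,
              x$metadata$grid_step))
  s <- x$summary
  if (s$flat) {
    cat("  outcome flat over start time (no circadian leverage)\n")
  } else {
    cat(sprintf("  best start %05.2f h (refined %05.2f), worst %05.2f h (refined %05.2f)\n",
                s$best, s$best_refined, s$worst, s$worst_refined))
  }
  invisible(x)
}

#' Write a 1-D outcome scan as CSV plus a JSON summary
#'
#' @param scan a `time_scan` from [scan_treatment_time()].
#' @param path output CSV path (`<path>.json` gets the summary).
#' @return `path`, invisibly.
#' @export
write_time_scan <- function(scan, path) {
  write.csv(scan$grid, path, row.names = FALSE)
  jsonlite::write_json(list(summary = scan$summary,
                            metadata = scan$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
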