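## Reproductions of the model's computational experiments: outcome scans
## over administration time, S-phase duration and inter-administration
## interval, the best/worst-times table, and preset calibration.

# root of lambda = -(kappa + gamma_eff) + coef * exp(-lambda * T)
char_root <- function(kappa, gamma_eff, Tbar, coef) {
  g <- function(l) -(kappa + gamma_eff) + coef * exp(-l * Tbar) - l
  uniroot(g, lower = -(kappa + gamma_eff + 2), upper = 10, tol = 1e-13)$root
}

# mean per-division survival and perturbation integral under the daily
# hazard of `sched` placed at start time t0
survival_stats <- function(preset, circ, sched, t0) {
  prof <- daily_profile(preset, sched, t0)
  s_day <- function(t) stage_survival(t, preset, prof, circ)
  sbar <- day_average(s_day)
  I <- day_average(function(t) {
    te <- t - sgm_total_delay(t, preset, circ)
    (s_day(t) - sbar) * kappa_tilde(te, preset, circ)
  })
  list(sbar = sbar, I = I)
}

# predicted treated growth rate lambda(t0) for one population
tato_growth_curve <- function(preset, circ, sched, starts,
                              g1_wave = NULL) {
  kap <- preset$kappa_mean
  Tbar <- preset$ts + preset$tg2_mean + preset$tm
  if (sched$target_phase == "G1") {
    if (is.null(g1_wave)) g1_wave <- g1_daily_profile(preset, circ)
    sig <- exp(-(preset$death_s * preset$ts +
                   preset$death_g2 * preset$tg2_mean +
                   preset$death_m * preset$tm))
    dbar <- flat_equivalent_rate(sched)
    lam0 <- char_root(kap, preset$g1_loss_rate + dbar, Tbar, 2 * sig * kap)
    vapply(starts, function(t0)
      lam0 + g1_growth_contribution(preset, circ, sched, t0, g1_wave),
      numeric(1))
  } else {
    vapply(starts, function(t0) {
      st <- survival_stats(preset, circ, sched, t0)
      char_root(kap, preset$g1_loss_rate, Tbar,
                2 * (st$sbar * kap + st$I))
    }, numeric(1))
  }
}

#' TATO prediction of the best and worst treatment times for a host--tumor
#' pair
#'
#' Combines the per-population perturbation analysis into an analytic
#' analogue of the simulated outcome score: for each administration time
#' the predicted treated growth rates of host and tumor (mean daily hazard
#' plus perturbation integral, through the characteristic equation) are
#' converted to predicted responses over the course duration, and the
#' predicted outcome `R_H - R_C` is maximized/minimized over the clock.
#'
#' @param host_preset,tumor_preset [cell_cycle_preset()]s.
#' @param circ a [circadian_input()].
#' @param sched a [schedule()] (interval 24 h).
#' @param grid_step start-time grid (h).
#' @param g1_waves optional named list with entries `host`, `tumor`
#'   ([g1_daily_profile()] functions), used for G1-targeted drugs.
#' @return a list with `best`, `worst` (refined clock times, h), `curve`
#'   (data.frame `start_time`, `score`).
#' @export
tato_outcome_extrema <- function(host_preset, tumor_preset,
                                 circ = circadian_input(),
                                 sched = schedule(), grid_step = 0.25,
                                 g1_waves = list()) {
  starts <- seq(0, 24 - grid_step, by = grid_step)
  t_course <- sched$n_admin * sched$interval
  lam_h <- tato_growth_curve(host_preset, circ, sched, starts,
                             g1_waves$host)
  lam_c <- tato_growth_curve(tumor_preset, circ, sched, starts,
                             g1_waves$tumor)
  r_h <- exp((lam_h - characteristic_growth_rate(host_preset)) * t_course)
  r_c <- exp((lam_c - characteristic_growth_rate(tumor_preset)) * t_course)
  score <- minmax_scale(r_h) - minmax_scale(r_c)
  ib <- which.max(score)
  iw <- which.min(score)
  list(best = refine_extremum(starts, score, ib),
       worst = refine_extremum(starts, -score, iw),
       curve = data.frame(start_time = starts, score = score))
}

#' Best and worst treatment times: simulation versus TATO
#'
#' For each drug target phase (G1, S, G2/M) and each tumor preset, finds
#' the administration clock times that maximize and minimize the simulated
#' outcome score ([scan_treatment_time()], 0.5 h grid with quadratic
#' refinement) and the corresponding analytic predictions
#' ([tato_outcome_extrema()]).  Plateaus (score within `plateau_tol` of the
#' extremum over a wider arc) are reported as ranges.
#'
#' @param host_preset host [cell_cycle_preset()].
#' @param tumor_presets named list of tumor presets.
#' @param circ a [circadian_input()].
#' @param sched_template a [schedule()]; target phase is overridden per
#'   row.
#' @param grid_step simulation scan grid (h).
#' @param dt integration step (h).
#' @param plateau_tol plateau tolerance on the score.
#' @return a data.frame with one row per phase x tumor: `phase`, `tumor`,
#'   `best_sim`, `worst_sim`, `best_tato`, `worst_tato` (clock hours,
#'   quadratic-refined), plateau flags/ranges; the underlying scans are
#'   attached as the `"scans"` attribute.
#' @export
best_worst_table <- function(host_preset, tumor_presets,
                             circ = circadian_input(),
                             sched_template = schedule(),
                             grid_step = 0.5, dt = 0.01,
                             plateau_tol = 1e-3) {
  stopifnot(is.list(tumor_presets), length(names(tumor_presets)) ==
              length(tumor_presets))
  phases <- c("G1", "S", "G2M")
  g1_waves_cache <- list()
  get_wave <- function(key, preset) {
    if (is.null(g1_waves_cache[[key]]))
      g1_waves_cache[[key]] <<- g1_daily_profile(preset, circ)
    g1_waves_cache[[key]]
  }
  rows <- list()
  scans <- list()
  for (ph in phases) {
    sched <- sched_template
    sched$target_phase <- ph
    for (tn in names(tumor_presets)) {
      tp <- tumor_presets[[tn]]
      sc <- scan_treatment_time(host_preset, tp, circ, sched,
                                grid_step = grid_step, dt = dt,
                                plateau_tol = plateau_tol)
      waves <- if (ph == "G1")
        list(host = get_wave("host", host_preset),
             tumor = get_wave(tn, tp)) else list()
      ta <- tato_outcome_extrema(host_preset, tp, circ, sched,
                                 g1_waves = waves)
      s <- sc$summary
      rows[[paste(ph, tn)]] <- data.frame(
        phase = ph, tumor = tn,
        best_sim = s$best_refined, worst_sim = s$worst_refined,
        best_tato = ta$best, worst_tato = ta$worst,
        best_plateau = !is.null(s$best_plateau) &&
          s$best_plateau$width_h > 2,
        worst_plateau = !is.null(s$worst_plateau) &&
          s$worst_plateau$width_h > 2,
        stringsAsFactors = FALSE)
      scans[[paste(ph, tn)]] <- sc
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scans") <- scans
  out
}

#' Scan the host response over S-phase duration and treatment time
#'
#' For each S-phase duration in `ts_grid`, evaluates (a) the perturbation
#' integral and (b) the full-simulation response over the administration
#' clock times in `time_grid`, each matrix min-max normalized to `[0, 1]`
#' over the whole grid, together with the closed-form extrema curves.
#'
#' @param preset_base the population preset (its `ts` is replaced).
#' @param circ a [circadian_input()].
#' @param sched_template an S-phase [schedule()].
#' @param ts_grid S-phase durations (h).
#' @param time_grid administration clock times (h).
#' @param dt integration step for the full simulations (h).
#' @return an object of class `duration_scan`: list with `ts_grid`,
#'   `time_grid`, `tato` and `sim` (matrices, rows = time, cols = ts),
#'   `tato_raw`, `sim_raw`, and `extrema` (closed-form kill/spare times
#'   per ts).
#' @export
scan_duration_vs_time <- function(preset_base, circ = circadian_input(),
                                  sched_template = schedule(),
                                  ts_grid = seq(2, 30, by = 1),
                                  time_grid = seq(0, 23.5, by = 0.5),
                                  dt = 0.02) {
  stopifnot(sched_template$target_phase == "S")
  tato <- sim <- matrix(NA_real_, length(time_grid), length(ts_grid),
                        dimnames = list(NULL, paste0("ts", ts_grid)))
  ex <- data.frame(ts = ts_grid, kill = NA_real_, spare = NA_real_)
  for (j in seq_along(ts_grid)) {
    p <- preset_base
    p$ts <- ts_grid[j]
    validate_preset(p)
    tato[, j] <- growth_contribution_curve(p, circ, sched_template,
                                           time_grid)
    un <- simulate_population(p, circ, NULL,
                              t_end = first_admin_time(sched_template) +
                                24 + 168 + 1, dt = dt)
    for (i in seq_along(time_grid)) {
      s <- sched_template
      s$start_time <- time_grid[i]
      sim[i, j] <- response(p, circ, s, dt = dt, untreated = un)
    }
    pred <- s_phase_extrema(p$kappa_mod_phase, p$ts)
    if (!pred$degenerate) {
      ex$kill[j] <- pred$best_time
      ex$spare[j] <- pred$worst_time
    }
  }
  norm01 <- function(m) (m - min(m)) / max(diff(range(m)), 1e-300)
  structure(list(ts_grid = ts_grid, time_grid = time_grid,
                 tato = norm01(tato), sim = norm01(sim),
                 tato_raw = tato, sim_raw = sim, extrema = ex,
                 metadata = list(preset = preset_base$label, dt = dt)),
            class = "duration_scan")
}

#' Scan the outcome over administration interval and first-day start time
#'
#' Simulates one course (fixed number of administrations, identical pulse
#' shape and total dose) for every combination of inter-administration
#' interval and first-day administration time, and scores host versus
#' tumor.  Following the reference figure, the responses are min-max
#' scaled over the whole grid before differencing; the raw score is kept
#' alongside.
#'
#' @param host_preset,tumor_preset [cell_cycle_preset()]s.
#' @param circ a [circadian_input()].
#' @param sched_template a [schedule()]; interval and start time are
#'   replaced per grid point.
#' @param interval_grid intervals between administrations (h).
#' @param start_grid first-day administration clock times (h).
#' @param dt integration step (h).
#' @return an object of class `interval_scan`: list with the grids, the
#'   `score` matrix (scaled responses; rows = start, cols = interval),
#'   `score_raw`, `r_host`, `r_tumor`, and `amplitude` (per-interval
#'   max - min of the scaled score over start).
#' @export
scan_interval_vs_start <- function(host_preset, tumor_preset,
                                   circ = circadian_input(),
                                   sched_template = schedule(),
                                   interval_grid = seq(16, 32, by = 0.4),
                                   start_grid = seq(0, 23, by = 1),
                                   dt = 0.02) {
  t_end <- first_admin_time(sched_template) + 24 + 168 + 1
  un_h <- simulate_population(host_preset, circ, NULL, t_end = t_end,
                              dt = dt)
  un_c <- simulate_population(tumor_preset, circ, NULL, t_end = t_end,
                              dt = dt)
  nr <- length(start_grid)
  nc <- length(interval_grid)
  r_h <- r_c <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    s <- sched_template
    s$interval <- interval_grid[j]
    s$start_time <- start_grid[i]
    r_h[i, j] <- response(host_preset, circ, s, dt = dt, untreated = un_h)
    r_c[i, j] <- response(tumor_preset, circ, s, dt = dt, untreated = un_c)
  }
  norm01 <- function(m) (m - min(m)) / max(diff(range(m)), 1e-300)
  score <- norm01(r_h) - norm01(r_c)
  amp <- apply(score, 2, function(x) diff(range(x)))
  structure(list(interval_grid = interval_grid, start_grid = start_grid,
                 score = score, score_raw = r_h - r_c,
                 r_host = r_h, r_tumor = r_c, amplitude = amp,
                 best_start = start_grid[apply(score, 2, which.max)],
                 metadata = list(host = host_preset$label,
                                 tumor = tumor_preset$label,
                                 n_admin = sched_template$n_admin,
                                 dt = dt)),
            class = "interval_scan")
}

#' Write a 2-D scan (duration or interval) as CSV plus a JSON manifest
#'
#' The value matrix goes to `path` in long format; axes, metadata and all
#' preset/schedule parameters needed to re-run the scan bit-identically go
#' to `<path>.json`.
#'
#' @param scan a `duration_scan` or `interval_scan`.
#' @param path output CSV path.
#' @param preset,sched optionally, the exact preset and schedule objects
#'   used, embedded in the manifest.
#' @return `path`, invisibly.
#' @export
write_scan_grid <- function(scan, path, preset = NULL, sched = NULL) {
  if (inherits(scan, "duration_scan")) {
    long <- expand.grid(start_time = scan$time_grid, ts = scan$ts_grid)
    long$tato <- as.vector(scan$tato)
    long$sim <- as.vector(scan$sim)
  } else {
    long <- expand.grid(start_time = scan$start_grid,
                        interval = scan$interval_grid)
    long$score <- as.vector(scan$score)
    long$r_host <- as.vector(scan$r_host)
    long$r_tumor <- as.vector(scan$r_tumor)
  }
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(metadata = scan$metadata,
                            preset = if (!is.null(preset)) unclass(preset),
                            schedule = if (!is.null(sched)) unclass(sched)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

## ---- preset calibration -------------------------------------------------

#' Daily S-phase fraction statistics of the untreated population
#'
#' Simulates the clock-gated untreated population, folds the post-transient
#' S-phase fraction onto clock time, and extracts its daily minimum,
#' maximum and peak clock time.
#'
#' @param preset a [cell_cycle_preset()].
#' @param circ a [circadian_input()].
#' @param dt integration step (h).
#' @param t_end simulation horizon (h); statistics use `[t_end - 48,
#'   t_end]`.
#' @return list with `smin`, `smax`, `peak` (clock h) and the folded
#'   profile.
#' @export
s_fraction_stats <- function(preset, circ = circadian_input(), dt = 0.02,
                             t_end = 144) {
  tr <- simulate_population(preset, circ, NULL, t_end = t_end, dt = dt)
  fr <- phase_fractions(tr)
  sel <- fr$time >= t_end - 48
  ct <- clock_time(fr$time[sel])
  fs <- fr$frac_s[sel]
  grid <- seq(0, 24 - 0.1, by = 0.1)
  idx <- floor(ct / 0.1) %% length(grid) + 1
  prof <- as.numeric(tapply(fs, factor(idx, levels = seq_along(grid)),
                            mean))
  ipk <- which.max(prof)
  list(smin = min(prof), smax = max(prof),
       peak = refine_extremum(grid, prof, ipk),
       clock = grid, profile = prof)
}

#' Calibrate one preset against daily S-phase fraction targets
#'
#' Tunes the G1-S transition parameters (`kappa_mean`, `kappa_mod_amp` and,
#' when a peak-time target is given, `kappa_mod_phase`) of a base preset by
#' derivative-free (Nelder-Mead) least squares so that the untreated,
#' clock-gated population reproduces a target daily S-phase fraction range
#' and (optionally) peak clock time.  Deterministic: fixed starting point
#' and optimizer settings, no randomness.  If the base preset already meets
#' the targets within `tol`, it is returned unchanged (calibration is a
#' fixed point).
#'
#' @param base a [cell_cycle_preset()] starting point.
#' @param target list with `smin`, `smax` (fractions) and optionally
#'   `peak` (clock h).
#' @param circ a [circadian_input()].
#' @param dt integration step for the calibration runs (h).
#' @param tol residual tolerance: maximum acceptable absolute error on the
#'   fraction targets (`tol`) and on the peak time (`tol_peak`, h).
#' @param tol_peak see `tol`.
#' @param maxit Nelder-Mead iteration cap.
#' @return the calibrated `cell_cycle_preset` with a `"calibration"`
#'   attribute (achieved statistics, residuals, convergence info); errors
#'   if the residual exceeds the tolerance.
#' @export
calibrate_preset <- function(base, target, circ = circadian_input(),
                             dt = 0.02, tol = 0.02, tol_peak = 1,
                             maxit = 300) {
  fit_phase <- !is.null(target$peak)
  mk <- function(par) {
    p <- base
    p$kappa_mean <- exp(par[1])
    p$kappa_mod_amp <- 0.95 * plogis(par[2])
    if (fit_phase) p$kappa_mod_phase <- clock_time(par[3])
    p
  }
  residuals <- function(stats) {
    r <- c(smin = stats$smin - target$smin,
           smax = stats$smax - target$smax)
    if (fit_phase) {
      d <- (stats$peak - target$peak + 12) %% 24 - 12
      r <- c(r, peak = d)
    }
    r
  }
  loss <- function(par) {
    p <- tryCatch(mk(par), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    st <- s_fraction_stats(p, circ, dt = dt)
    r <- residuals(st)
    sum((r * c(1, 1, 1 / 24)[seq_along(r)])^2)
  }
  ok <- function(r, f = 1) all(abs(r[c("smin", "smax")]) <= tol * f) &&
    (!fit_phase || abs(r[["peak"]]) <= tol_peak * f)

  par0 <- c(log(base$kappa_mean),
            qlogis(min(max(base$kappa_mod_amp / 0.95, 1e-3), 1 - 1e-3)),
            if (fit_phase) base$kappa_mod_phase)
  st0 <- s_fraction_stats(base, circ, dt = dt)
  r0 <- residuals(st0)
  if (ok(r0, f = 0.25)) {
    attr(base, "calibration") <- list(converged = TRUE, moved = FALSE,
                                      achieved = st0[1:3], residuals = r0,
                                      target = target)
    return(base)
  }
  opt <- optim(par0, loss, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  cal <- mk(opt$par)
  st <- s_fraction_stats(cal, circ, dt = dt)
  r <- residuals(st)
  if (!ok(r))
    stop("calibration failed: residuals ",
         paste(sprintf("%s=%.4g", names(r), r), collapse = ", "),
         " exceed tolerance")
  attr(cal, "calibration") <- list(converged = opt$convergence == 0,
                                   moved = TRUE, achieved = st[1:3],
                                   residuals = r, target = target,
                                   loss = opt$value)
  cal
}

#' Calibrate and write the shipped preset family
#'
#' Runs [calibrate_preset()] for each named target/base pair and writes the
#' resulting presets as YAML files together with a JSON calibration report
#' (targets, achieved values, residuals).  No preset file is written for a
#' population whose calibration fails.
#'
#' @param targets named list of target specs (see [calibrate_preset()]).
#' @param bases named list of base presets (same names).
#' @param out_dir output directory for `<name>.yaml` files and
#'   `calibration_report.json`.
#' @param ... passed to [calibrate_preset()].
#' @return named list of calibrated presets, invisibly.
#' @export
calibrate_presets <- function(targets, bases, out_dir, ...) {
  stopifnot(identical(sort(names(targets)), sort(names(bases))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- list()
  report <- list()
  for (nm in names(targets)) {
    cal <- calibrate_preset(bases[[nm]], targets[[nm]], ...)
    save_preset(cal, file.path(out_dir, paste0(nm, ".yaml")))
    out[[nm]] <- cal
    report[[nm]] <- attr(cal, "calibration")
  }
  jsonlite::write_json(report, file.path(out_dir,
                                         "calibration_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
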