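PRESET_FIELDS <- c("kappa_mean", "g1_loss_rate", "ts", "tg2_mean", "tm",
                   "death_s", "death_g2", "death_m",
                   "kappa_mod_amp", "kappa_mod_phase",
                   "g2_mod_amp", "g2_mod_phase", "label")

#' Cell-cycle kinetic preset
#'
#' All kinetic and circadian-coupling parameters for one cell population
#' (host or tumor).  The cell cycle has four compartments: a G0/G1 phase of
#' exponentially distributed duration (exit rate `kappa_mean`, clock-gated),
#' followed by S, G2 and M phases of fixed duration.  The G1-S transition
#' rate and the G2 duration carry a sinusoidal daily modulation:
#' \deqn{\kappa(t) = \bar\kappa\,[1 + a_\kappa \cos(2\pi (t - t_\kappa)/24)]}
#' \deqn{T_{G2}(t) = \bar T_{G2}\,[1 + a_{G2} \cos(2\pi (t - t_{G2})/24)]}
#'
#' @param kappa_mean mean G1-to-S transition rate (1/h).
#' @param g1_loss_rate permanent G1 exit (differentiation/death) rate (1/h).
#' @param ts S phase duration (h).
#' @param tg2_mean mean G2 phase duration (h).
#' @param tm M phase duration (h).
#' @param death_s,death_g2,death_m basal apoptosis rates in S, G2, M (1/h).
#' @param kappa_mod_amp relative modulation amplitude of the G1-S rate,
#'   in `[0, 1)`.
#' @param kappa_mod_phase clock time of the daily G1-S rate peak (h).
#' @param g2_mod_amp relative modulation amplitude of the G2 duration,
#'   in `[0, 1)`.
#' @param g2_mod_phase clock time of the daily G2-duration peak (h).
#' @param label short name for the preset.
#' @return an object of class `cell_cycle_preset`.
#' @details The parameters must keep the total S+G2+M transit time
#'   `T(t) = ts + T_G2(t) + tm` slowly varying: `|dT/dt| < 1` over the day
#'   (delay monotonicity), so that cohorts divide in the order in which they
#'   entered S phase.  The constructor rejects violations.
#' @seealso [load_preset()], [shipped_preset()]
#' @export
cell_cycle_preset <- function(kappa_mean, g1_loss_rate = 0.01,
                              ts = 9, tg2_mean = 3, tm = 1,
                              death_s = 0.001, death_g2 = 0.001,
                              death_m = 0.001,
                              kappa_mod_amp = 0, kappa_mod_phase = 14,
                              g2_mod_amp = 0, g2_mod_phase = 14,
                              label = "preset") {
  p <- list(kappa_mean = kappa_mean, g1_loss_rate = g1_loss_rate,
            ts = ts, tg2_mean = tg2_mean, tm = tm,
            death_s = death_s, death_g2 = death_g2, death_m = death_m,
            kappa_mod_amp = kappa_mod_amp,
            kappa_mod_phase = clock_time(kappa_mod_phase),
            g2_mod_amp = g2_mod_amp,
            g2_mod_phase = clock_time(g2_mod_phase),
            label = as.character(label))
  validate_preset(p)
  structure(p, class = "cell_cycle_preset")
}

validate_preset <- function(p) {
  num <- setdiff(PRESET_FIELDS, "label")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("preset field '%s' must be a finite number", f))
  }
  rates <- c("kappa_mean", "g1_loss_rate", "death_s", "death_g2", "death_m")
  if (any(unlist(p[rates]) < 0)) stop("all rates must be >= 0")
  if (any(unlist(p[c("ts", "tg2_mean", "tm")]) <= 0))
    stop("all phase durations must be > 0")
  if (p$kappa_mod_amp < 0 || p$kappa_mod_amp >= 1)
    stop("kappa_mod_amp must be in [0, 1)")
  if (p$g2_mod_amp < 0 || p$g2_mod_amp >= 1)
    stop("g2_mod_amp must be in [0, 1) (T_G2 would reach 0)")
  # delay monotonicity: |T'(t)| = tg2_mean * a_g2 * 2*pi/24 < 1
  tprime_max <- p$tg2_mean * p$g2_mod_amp * 2 * pi / 24
  if (tprime_max >= 1)
    stop(sprintf(paste0("G2 modulation too strong: max |dT/dt| = %.3g >= 1; ",
                        "cohort ordering would break"), tprime_max))
  invisible(p)
}

#' @export
print.cell_cycle_preset <- function(x, ...) {
  cat(sprintf("<cell_cycle_preset> '%s'\n", x$label))
  cat(sprintf("  kappa: %.4g /h (amp %.3g, peak %05.2f h); G1 loss %.4g /h\n",
              x$kappa_mean, x$kappa_mod_amp, x$kappa_mod_phase,
              x$g1_loss_rate))
  cat(sprintf("  durations: S %g h, G2 %g h (amp %.3g, peak %05.2f h), M %g h\n",
              x$ts, x$tg2_mean, x$g2_mod_amp, x$g2_mod_phase, x$tm))
  cat(sprintf("  basal death: S %.4g, G2 %.4g, M %.4g /h\n",
              x$death_s, x$death_g2, x$death_m))
  invisible(x)
}

#' Switch the circadian gating off
#'
#' Returns a copy of the preset with both modulation amplitudes set to zero
#' (free-running, asynchronous growth).
#'
#' @param preset a [cell_cycle_preset()].
#' @return a `cell_cycle_preset` with `kappa_mod_amp = g2_mod_amp = 0`.
#' @export
clock_off <- function(preset) {
  preset$kappa_mod_amp <- 0
  preset$g2_mod_amp <- 0
  preset
}

#' Read a cell-cycle preset from YAML
#'
#' The file must be a flat mapping whose keys are exactly the
#' [cell_cycle_preset()] field names; unknown keys are rejected and the
#' usual invariants are enforced.
#'
#' @param path path to a YAML file.
#' @return a `cell_cycle_preset`.
#' @export
load_preset <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), PRESET_FIELDS)
  if (length(unknown))
    stop("unknown preset keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(setdiff(PRESET_FIELDS, "label"), names(y))
  if (length(missing))
    stop("missing preset keys: ", paste(missing, collapse = ", "))
  do.call(cell_cycle_preset, y)
}

#' Write a cell-cycle preset to YAML
#'
#' @param preset a [cell_cycle_preset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_preset <- function(preset, path) {
  yaml::write_yaml(unclass(preset)[PRESET_FIELDS], path)
  invisible(path)
}

#' Calibrated presets shipped with the package
#'
#' Loads one of the three calibrated kinetic presets: `"host"` (bone-marrow
#' blood progenitors), `"tumor_fast"` (fast-growing colorectal tumor, short
#' S phase) or `"tumor_slow"` (slow-growing colorectal tumor, long S phase).
#' The presets were calibrated with [calibrate_presets()] so that the
#' untreated, clock-gated populations reproduce the daily S-phase fraction
#' ranges of the three reference tissues (host 20--30% peaking near 12:00,
#' fast tumor 15--30%, slow tumor 42--47%).
#'
#' @param name one of `"host"`, `"tumor_fast"`, `"tumor_slow"`.
#' @return a `cell_cycle_preset`.
#' @export
shipped_preset <- function(name = c("host", "tumor_fast", "tumor_slow")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "chronocycle", mustWork = TRUE)
  load_preset(path)
}
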