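#' Circadian input
#'
#' Container for the sinusoidal circadian signal
#' \deqn{C(t) = 1 + a \cos\left(\frac{2\pi (t - \psi)}{24}\right)}
#' that gates the cell cycle.  `C(t)` mimics the typical daily expression
#' profile of clock-controlled genes: it is 24 h periodic, averages to 1 over
#' one day, and peaks at clock time `phase_shift`.
#'
#' @param amplitude_coeff relative amplitude `a` (dimensionless, `0 <= a < 1`).
#'   Default 0.2.
#' @param phase_shift peak clock time `psi` in hours-of-day (`0 <= psi < 24`).
#'   Default 14.
#' @param period circadian period in hours; fixed at 24.
#' @return an object of class `circadian_input`.
#' @examples
#' circ <- circadian_input()
#' circadian_modulation(14, circ)  # 1.2, the daily peak
#' @export
circadian_input <- function(amplitude_coeff = 0.2, phase_shift = 14,
                            period = 24) {
  stopifnot(is.numeric(amplitude_coeff), length(amplitude_coeff) == 1L,
            amplitude_coeff >= 0, amplitude_coeff < 1)
  stopifnot(is.numeric(phase_shift), length(phase_shift) == 1L,
            phase_shift >= 0, phase_shift < 24)
  if (!isTRUE(all.equal(period, 24)))
    stop("the circadian period is fixed at 24 h")
  structure(list(amplitude_coeff = amplitude_coeff,
                 phase_shift = phase_shift,
                 period = 24),
            class = "circadian_input")
}

#' @export
print.circadian_input <- function(x, ...) {
  cat(sprintf("<circadian_input> amplitude %.3g, peak at %05.2f h, period %g h\n",
              x$amplitude_coeff, x$phase_shift, x$period))
  invisible(x)
}

#' Circadian modulation factor
#'
#' Evaluates the circadian signal `C(t)` at (absolute) time `t`.
#'
#' @param t time in hours; interpreted modulo 24.
#' @param circ a [circadian_input()].
#' @return dimensionless factor, `1 + a*cos(2*pi*(t - psi)/24)`.
#' @export
circadian_modulation <- function(t, circ = circadian_input()) {
  1 + circ$amplitude_coeff *
    cos(2 * pi * (t - circ$phase_shift) / circ$period)
}
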