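#' @useDynLib ftacv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# physical constants (CODATA)
.FARADAY <- 96485.33212     # C mol^-1
.GAS_R <- 8.31446261815324  # J mol^-1 K^-1

#' FTACV potential program specification
#'
#' Describes the applied potential of a large-amplitude AC voltammetry
#' experiment: a triangular dc ramp from `E_start` to `E_reverse` and back at
#' scan rate `v`, with a superimposed sine wave of amplitude `dE`, frequency
#' `f` and phase `eta`, i.e. \eqn{E(t) = E_{dc}(t) + \Delta E \sin(\omega t +
#' \eta)} with \eqn{\omega = 2\pi f}.
#'
#' @param E_start,E_reverse dc ramp start and reversal potentials (V vs.
#'   reference). Must differ when `v > 0`.
#' @param v dc scan rate magnitude (V s^-1); the sweep direction follows the
#'   sign of `E_reverse - E_start`.
#' @param dE sine amplitude \eqn{\Delta E} (V).
#' @param f sine frequency (Hz). Also sets the output sampling rate via
#'   `samples_per_period`.
#' @param eta sine phase (rad).
#' @param samples_per_period output samples per ac period; at least 200 so
#'   that nine and more harmonics are comfortably below the Nyquist frequency.
#' @return An object of class `"waveform_spec"`.
#' @examples
#' w <- waveform_spec(E_start = 0.05, E_reverse = -0.45)
#' ftacv_potential(0.1, w)
#' @export
waveform_spec <- function(E_start, E_reverse, v = 0.0224, dE = 0.150,
                          f = 8.96, eta = 0, samples_per_period = 400) {
  stopifnot(is.finite(E_start), is.finite(E_reverse), is.finite(v),
            is.finite(dE), is.finite(f), is.finite(eta))
  if (f <= 0) stop("'f' must be > 0")
  if (dE < 0) stop("'dE' must be >= 0")
  if (v < 0) stop("'v' is a magnitude; use E_start/E_reverse for direction")
  if (samples_per_period < 200)
    stop("'samples_per_period' must be >= 200 (anti-aliasing for >= 9 harmonics)")
  if (v > 0 && E_start == E_reverse)
    stop("'E_start' and 'E_reverse' must differ when v > 0")
  w <- list(E_start = E_start, E_reverse = E_reverse, v = v, dE = dE, f = f,
            eta = eta, samples_per_period = as.integer(samples_per_period))
  class(w) <- "waveform_spec"
  w
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat("FTACV waveform: ", x$E_start, " V -> ", x$E_reverse, " V -> ",
      x$E_start, " V at ", x$v * 1e3, " mV/s\n", sep = "")
  cat("  sine: dE = ", x$dE * 1e3, " mV, f = ", x$f, " Hz, eta = ", x$eta,
      " rad; ", x$samples_per_period, " samples/period\n", sep = "")
  invisible(x)
}

# time at which the dc ramp reverses, and the full sweep duration
t_switch <- function(w) abs(w$E_start - w$E_reverse) / w$v
t_end <- function(w) 2 * t_switch(w)

#' dc component of the FTACV potential program
#'
#' Triangular ramp: moves from `E_start` towards `E_reverse` at rate `v`,
#' reverses at `E_reverse` and returns; continuous and piecewise linear.
#'
#' @param t time (s), within `[0, 2 |E_start - E_reverse| / v]`.
#' @param w a [waveform_spec()].
#' @return dc potential (V), vectorized over `t`.
#' @export
dc_ramp <- function(t, w) {
  stopifnot(inherits(w, "waveform_spec"))
  ts <- t_switch(w)
  if (any(!is.finite(t)) || any(t < -1e-12) || any(t > 2 * ts + 1e-9))
    stop("'t' outside the sweep duration [0, ", format(2 * ts), "] s")
  sgn <- sign(w$E_reverse - w$E_start)
  ifelse(t <= ts, w$E_start + sgn * w$v * t,
         w$E_reverse - sgn * w$v * (t - ts))
}

#' Applied FTACV potential
#'
#' `dc_ramp(t, w) + dE * sin(2 pi f t + eta)`.
#'
#' @inheritParams dc_ramp
#' @return applied potential (V), vectorized over `t`.
#' @export
ftacv_potential <- function(t, w) {
  dc_ramp(t, w) + w$dE * sin(2 * pi * w$f * t + w$eta)
}

# per-sample sweep flag on the dc ramp: "forward" before reversal
dc_direction <- function(t, w) {
  ifelse(t <= t_switch(w), "forward", "reverse")
}
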