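#' Harmonic decomposition of a current trace
#'
#' Isolates the aperiodic (dc) component and the n-th harmonic time-domain
#' currents by the classical FTACV sequence: Fourier transformation of the
#' total current, rectangular band selection about each multiple of the
#' fundamental frequency, and inverse transformation. For order `n >= 1` the
#' band is `[n f - w, n f + w]` together with its negative-frequency mirror;
#' order 0 keeps `[0, w]`. The magnitude envelope of each harmonic is twice
#' the modulus of the analytic (one-sided) band signal.
#'
#' @param trace an `"ftacv_trace"` (or any data frame with `t_s` and the
#'   `current` column), uniformly sampled.
#' @param orders integer harmonic orders; 0 is the aperiodic component.
#' @param band_halfwidth half-width of the selection band (Hz); must be
#'   `< f/2` so bands do not overlap. Default `0.45 f`.
#' @param f fundamental frequency (Hz); taken from the trace waveform when
#'   omitted.
#' @param current name of the current column to decompose.
#' @return A `"harmonic_set"`: list with `orders`, `signals` (matrix, one
#'   column per order), `envelopes`, `t`, `f`, `band_halfwidth`.
#' @export
extract_harmonics <- function(trace, orders = 0:9, band_halfwidth = NULL,
                              f = NULL, current = "I_total_A") {
  if (is.null(f)) {
    w <- attr(trace, "waveform")
    if (is.null(w)) stop("'f' must be given when the trace carries no waveform")
    f <- w$f
  }
  if (is.null(band_halfwidth)) band_halfwidth <- 0.45 * f
  if (band_halfwidth >= f / 2)
    stop("'band_halfwidth' must be < f/2 (non-overlapping bands)")
  t <- trace$t_s
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9 * stats::median(dt))
    stop("trace must be uniformly sampled")
  dt <- stats::median(dt)
  fs <- 1 / dt
  if (fs / 2 <= max(orders) * f + band_halfwidth)
    stop("Nyquist frequency too low for the requested orders")
  x <- trace[[current]]
  n <- length(x)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) / (n * dt)         # 0 .. fs(1-1/n)
  fpos <- pmin(freq, fs - freq)               # folded frequency of each bin
  sig <- env <- matrix(0, n, length(orders))
  for (j in seq_along(orders)) {
    o <- orders[j]
    lo <- max(o * f - band_halfwidth, 0)
    hi <- o * f + band_halfwidth
    keep <- fpos >= lo & fpos <= hi
    if (o >= 1) {
      one_sided <- keep & freq <= fs / 2 & freq > 0
      z <- X
      z[!one_sided] <- 0
      a <- stats::fft(z, inverse = TRUE) / n   # analytic band signal
      sig[, j] <- 2 * Re(a)
      env[, j] <- 2 * Mod(a)
    } else {
      z <- X
      z[!keep] <- 0
      s <- Re(stats::fft(z, inverse = TRUE) / n)
      sig[, j] <- s
      env[, j] <- abs(s)
    }
  }
  colnames(sig) <- colnames(env) <- paste0("h", orders)
  structure(list(orders = orders, signals = sig, envelopes = env, t = t,
                 f = f, band_halfwidth = band_halfwidth),
            class = "harmonic_set")
}

#' @export
print.harmonic_set <- function(x, ...) {
  cat("Harmonic set: orders", paste(x$orders, collapse = ", "),
      "at f =", x$f, "Hz, band half-width", signif(x$band_halfwidth, 4), "Hz\n")
  pk <- apply(abs(x$signals), 2, max)
  print(signif(pk, 3))
  invisible(x)
}

#' Harmonic currents against the dc potential
#'
#' Tabulates each harmonic signal (and envelope) against the dc ramp
#' potential `Edc(t)` for current-potential plotting and residual
#' computation against a second harmonic set from the same grid.
#'
#' @param hs a `"harmonic_set"`.
#' @param w the [waveform_spec()] of the source trace.
#' @param reference optional second `"harmonic_set"` on the same grid; adds a
#'   `residual` column (`hs` minus `reference`).
#' @return long-format data frame with columns `order`, `t_s`, `E_dc_V`,
#'   `I_A`, `envelope_A` (and `residual_A`).
#' @export
harmonic_vs_dc_potential <- function(hs, w, reference = NULL) {
  stopifnot(inherits(hs, "harmonic_set"), inherits(w, "waveform_spec"))
  if (!is.null(reference)) {
    if (length(reference$t) != length(hs$t) ||
        !all(hs$orders %in% reference$orders))
      stop("'reference' must share the time grid and contain the same orders")
  }
  edc <- dc_ramp(hs$t, w)
  out <- do.call(rbind, lapply(seq_along(hs$orders), function(j) {
    d <- data.frame(order = hs$orders[j], t_s = hs$t, E_dc_V = edc,
                    I_A = hs$signals[, j], envelope_A = hs$envelopes[, j])
    if (!is.null(reference)) {
      k <- match(hs$orders[j], reference$orders)
      d$residual_A <- hs$signals[, j] - reference$signals[, k]
    }
    d
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.harmonic_set <- function(x, w = NULL, orders = x$orders, ...) {
  op <- graphics::par(mfrow = c(length(orders), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (o in orders) {
    j <- match(o, x$orders)
    graphics::plot(x$t, x$signals[, j] * 1e6, type = "l",
                   ylab = paste0("h", o, " / uA"), xlab = "", ...)
    if (o >= 1) graphics::lines(x$t, x$envelopes[, j] * 1e6, col = 2, lty = 2)
  }
  invisible(x)
}

# number of resolvable harmonics: envelope peak > `factor` times the noise
# floor estimated from the band midway between this harmonic and the next
resolvable_harmonics <- function(trace, f = NULL, max_order = 15,
                                 factor = 5, current = "I_total_A") {
  if (is.null(f)) f <- attr(trace, "waveform")$f
  t <- trace$t_s
  dt <- stats::median(diff(t))
  n <- length(t)
  x <- trace[[current]]
  X <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) / (n * dt)
  count <- 0L
  for (o in seq_len(max_order)) {
    if ((o + 0.5) * f > max(freq)) break
    pk <- max(X[freq >= (o - 0.25) * f & freq <= (o + 0.25) * f])
    floor_band <- X[(freq > (o + 0.35) * f & freq < (o + 0.65) * f) |
                    (freq > (o - 0.65) * f & freq < (o - 0.35) * f)]
    if (pk > factor * stats::median(floor_band)) count <- count + 1L else break
  }
  count
}

#' Export a harmonic set as a long-format table
#'
#' @param hs a `"harmonic_set"`.
#' @param w the source [waveform_spec()].
#' @param path CSV file path.
#' @return the written data frame, invisibly.
#' @export
write_harmonics <- function(hs, w, path) {
  d <- harmonic_vs_dc_potential(hs, w)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
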