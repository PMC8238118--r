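#' Select regions of a trace with little or no Faradaic contribution
#'
#' Returns the time windows, on both dc sweeps, where the dc potential is
#' further than `half_window` from `E_center` (a rough location of the redox
#' wave). These windows drive the first, time-domain step of the two-step
#' fitting procedure: the capacitance and uncompensated-resistance fit.
#'
#' @param trace an `"ftacv_trace"`.
#' @param E_center centre of the Faradaic wave (V); defaults to the midpoint
#'   of the dc window.
#' @param half_window half-width of the excluded potential band (V), `> 0`.
#' @return data frame of windows (`t_start_s`, `t_end_s`, `sweep`) with the
#'   logical sample mask attached as attribute `"mask"`.
#' @export
select_nonfaradaic_regions <- function(trace, E_center = NULL,
                                       half_window = 0.2) {
  w <- attr(trace, "waveform")
  if (is.null(w)) stop("trace carries no waveform specification")
  if (half_window < 0) stop("'half_window' must be >= 0")
  edc <- dc_ramp(trace$t_s, w)
  if (is.null(E_center)) E_center <- (w$E_start + w$E_reverse) / 2
  mask <- abs(edc - E_center) > half_window
  if (!any(mask))
    stop("no non-Faradaic samples survive; use a smaller 'half_window'")
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(t_start_s = trace$t_s[starts[keep]],
                    t_end_s = trace$t_s[ends[keep]],
                    sweep = dc_direction(trace$t_s[starts[keep]], w))
  attr(out, "mask") <- mask
  out
}

#' Fourier-domain Euclidean objective
#'
#' The Euclidean distance between the discrete Fourier transforms of the
#' simulated and measured total currents, restricted to frequencies in
#' `[0, (max_order + 1/2) f]` (real and imaginary parts). This is the
#' frequency-domain objective minimized in the second, Faradaic step of the
#' two-step fit.
#'
#' @param sim,obs traces on identical time grids.
#' @param f fundamental frequency (Hz); from the waveform when omitted.
#' @param max_order highest harmonic order retained.
#' @param min_order lowest harmonic order retained (0 keeps the aperiodic
#'   band; the Faradaic fit uses 1 so the slowly varying background ramp
#'   does not dominate the objective).
#' @param current current column used.
#' @return non-negative scalar objective value.
#' @export
fourier_objective <- function(sim, obs, f = NULL, max_order = 10,
                              min_order = 0, current = "I_total_A") {
  if (is.null(f)) f <- attr(sim, "waveform")$f
  ts <- sim$t_s; to <- obs$t_s
  if (length(ts) != length(to) || max(abs(ts - to)) > 1e-9)
    stop("'sim' and 'obs' must share the same time grid")
  d <- sim[[current]] - obs[[current]]
  n <- length(d)
  dt <- stats::median(diff(ts))
  freq <- (seq_len(n) - 1) / (n * dt)
  keep <- freq <= (max_order + 0.5) * f
  if (min_order > 0) keep <- keep & freq >= (min_order - 0.5) * f
  sqrt(sum(Mod(stats::fft(d)[keep])^2))
}

new_ftacv_fit <- function(model_tag, par, objective, opt, bounds, extra) {
  structure(c(list(model_tag = model_tag, best_params = par,
                   objective = objective,
                   restarts = opt$n_restarts,
                   per_restart = opt$per_restart,
                   bounds = bounds,
                   at_bound = stats::setNames(opt$at_bound, names(par))),
              extra),
            class = "ftacv_fit")
}

#' @export
print.ftacv_fit <- function(x, ...) {
  cat("FTACV fit (", x$model_tag, "), ", x$restarts, " restarts\n", sep = "")
  cat("  objective:", format(x$objective, digits = 6), "\n")
  p <- signif(x$best_params, 5)
  flag <- ifelse(x$at_bound, " [at bound]", "")
  for (i in seq_along(p))
    cat("  ", format(names(p)[i], width = 10), p[i], flag[i], "\n")
  invisible(x)
}

#' @export
coef.ftacv_fit <- function(object, ...) object$best_params

#' @export
summary.ftacv_fit <- function(object, ...) {
  vals <- vapply(object$per_restart, `[[`, numeric(1), "value")
  cat("Model:", object$model_tag, "\n")
  cat("Best objective:", format(object$objective, digits = 6),
      "over", length(vals), "successful restarts\n")
  cat("Restart objective spread:",
      paste(format(range(vals), digits = 6), collapse = " .. "), "\n")
  if (any(object$at_bound))
    cat("Parameters at a bound:",
        paste(names(object$best_params)[object$at_bound], collapse = ", "), "\n")
  invisible(object)
}

# serialize a fit (or comparison) as JSON
#' Write a fit result to JSON
#' @param x an `"ftacv_fit"` or `"model_comparison"`.
#' @param path output file.
#' @export
write_fit <- function(x, path) {
  ser <- function(f) list(
    model_tag = f$model_tag,
    best_params = as.list(f$best_params),
    objective = f$objective,
    restarts = f$restarts,
    at_bound = as.list(f$at_bound),
    bounds = apply(f$bounds, 1, function(b) as.list(b), simplify = FALSE))
  obj <- if (inherits(x, "model_comparison"))
    list(sequential = ser(x$sequential), concerted = ser(x$concerted),
         preferred = x$preferred)
  else ser(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
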