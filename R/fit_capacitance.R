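#' Time-domain capacitance and uncompensated-resistance fit
#'
#' First step of the two-step inverse problem: on the selected non-Faradaic
#' regions, minimizes the time-domain sum of squared differences between the
#' measured current and the capacitive-current model (dual cubic polynomial
#' capacitance with Ohmic-drop coupling, zero coverage).
#'
#' In Faradaic-free regions the measured current is entirely capacitive, so
#' for a trial resistance the effective potential is known exactly from the
#' data, `E_eff = E_app - Ru * I`, and the model current
#' `S c0 (1 + c1 E + c2 E^2 + c3 E^3) dE_eff/dt` is linear in the four
#' products `c0`, `c0 c1`, `c0 c2`, `c0 c3` of each sweep direction. Each of
#' the `n_restarts` optimizations therefore profiles the eight polynomial
#' coefficients out by exact least squares and minimizes over `Ru` alone
#' (bounded 1-d search started from a uniform random draw), which recovers
#' the weakly identified resistance far more reliably than a joint
#' 9-parameter derivative-free search.
#'
#' @param trace an `"ftacv_trace"` carrying its waveform.
#' @param regions output of [select_nonfaradaic_regions()]; defaults to
#'   region selection with the default window.
#' @param bounds optional named list of `c(lo, hi)` per parameter
#'   (`c0f..c3f`, `c0r..c3r`, `Ru`); only the `Ru` bounds steer the search,
#'   the rest flag out-of-range profiled coefficients.
#' @param n_restarts number of optimizations (default 10).
#' @param seed RNG seed for the restart draws.
#' @return An `"ftacv_fit"` with `model_tag = "capacitance"`. The fitted
#'   [cell_parameters()] (zero coverage) are stored as `$cell`.
#' @export
fit_capacitance <- function(trace, regions = NULL, bounds = NULL,
                            n_restarts = 10, seed = NULL) {
  w <- attr(trace, "waveform")
  if (is.null(w)) stop("trace carries no waveform specification")
  cell0 <- attr(trace, "cell")
  temperature <- if (!is.null(cell0)) cell0$temperature else 298.15
  S <- if (!is.null(cell0)) cell0$S else 0.03
  if (is.null(regions)) regions <- select_nonfaradaic_regions(trace)
  mask <- attr(regions, "mask")
  if (is.null(mask) || !any(mask)) stop("'regions' contain no samples")

  defaults <- list(c0f = c(0, 2e-3), c1f = c(-2, 2), c2f = c(-2, 2),
                   c3f = c(-2, 2), c0r = c(0, 2e-3), c1r = c(-2, 2),
                   c2r = c(-2, 2), c3r = c(-2, 2), Ru = c(0, 500))
  if (!is.null(bounds)) defaults[names(bounds)] <- bounds
  lo <- vapply(defaults, `[`, numeric(1), 1)
  hi <- vapply(defaults, `[`, numeric(1), 2)

  t <- trace$t_s
  dt <- stats::median(diff(t))
  n <- length(t)
  I <- trace$I_total_A
  Ea <- trace$E_applied_V
  fwd <- trace$dc_direction == "forward"
  # drop edge samples (one-sided derivative) and the reversal sample
  interior <- c(FALSE, rep(TRUE, n - 2), FALSE)

  # profiled SSE over Ru: coefficients by direction-wise least squares on
  # the data-derived effective potential
  profile_fit <- function(Ru) {
    Ee <- Ea - Ru * I
    dE <- c(NA, (Ee[3:n] - Ee[1:(n - 2)]) / (2 * dt), NA)
    sse <- 0
    coefs <- numeric(8)
    for (d in c(TRUE, FALSE)) {
      sel <- mask & interior & (if (d) fwd else !fwd)
      if (sum(sel) < 8) return(list(sse = Inf))
      X <- cbind(dE[sel], dE[sel] * Ee[sel], dE[sel] * Ee[sel]^2,
                 dE[sel] * Ee[sel]^3) * S
      fit <- stats::lm.fit(X, I[sel])
      b <- fit$coefficients
      b[is.na(b)] <- 0
      cc <- if (abs(b[1]) > 1e-300) c(b[1], b[2] / b[1], b[3] / b[1],
                                      b[4] / b[1]) else c(0, 0, 0, 0)
      if (d) coefs[1:4] <- cc else coefs[5:8] <- cc
      sse <- sse + sum(fit$residuals^2)
    }
    list(sse = sse, coefs = coefs)
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  per <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    Ru0 <- stats::runif(1, lo[["Ru"]], hi[["Ru"]])
    # bounded local search over Ru from the random start
    o <- stats::optim(Ru0, function(Ru) profile_fit(Ru)$sse,
                      method = "Brent", lower = lo[["Ru"]],
                      upper = hi[["Ru"]],
                      control = list(reltol = 1e-14))
    per[[r]] <- list(par = o$par, value = o$value)
  }
  vals <- vapply(per, `[[`, numeric(1), "value")
  if (!any(is.finite(vals))) stop("all optimizer restarts failed")
  Ru_hat <- per[[which.min(vals)]]$par
  pf <- profile_fit(Ru_hat)
  par <- stats::setNames(c(pf$coefs, Ru_hat), names(defaults))
  at_bound <- par <= lo + 1e-3 * (hi - lo) | par >= hi - 1e-3 * (hi - lo)
  opt <- list(n_restarts = n_restarts, per_restart = per,
              at_bound = at_bound)
  cell_fit <- cell_parameters(Ru = max(par[["Ru"]], 0),
                              temperature = temperature, S = S, Gamma = 0,
                              cap_forward = unname(pmin(pmax(par[1:4],
                                                             lo[1:4]),
                                                        hi[1:4])),
                              cap_reverse = unname(pmin(pmax(par[5:8],
                                                             lo[5:8]),
                                                        hi[5:8])))
  new_ftacv_fit("capacitance", par, pf$sse, opt, rbind(lo = lo, hi = hi),
                list(cell = cell_fit, waveform = w, regions = regions))
}
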