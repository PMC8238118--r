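# Multi-start bounded derivative-free minimizer.
#
# Nelder-Mead on the raw scale with box projection: candidate points outside
# the box are evaluated at their projection plus a quadratic penalty, so a
# plateau sloping towards a bound terminates exactly at the bound (the
# behaviour seen when a rate constant exceeds the experimentally resolvable
# range). Restart points are drawn uniformly inside the bounds; the best
# restart receives one polishing run.
multistart_optim <- function(fn, lower, upper, n_restarts = 10, seed = NULL,
                             maxit = 800, reltol = 1e-10, polish = TRUE,
                             extra_starts = NULL, rounds = 2) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            n_restarts >= 1)
  d <- length(lower)
  rng <- upper - lower
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pen_scale <- NA_real_
  wrap <- function(par) {
    proj <- pmin(pmax(par, lower), upper)
    val <- fn(proj)
    if (!is.finite(val)) return(1e300)
    if (is.na(pen_scale)) pen_scale <<- abs(val) + 1e-12
    val + 100 * pen_scale * sum(((par - proj) / rng)^2)
  }
  run_one <- function(p0) {
    if (d == 1) {
      o <- stats::optim(p0, wrap, method = "Brent", lower = lower,
                        upper = upper, control = list(maxit = maxit))
      par <- pmin(pmax(o$par, lower), upper)
      return(list(par = par, value = fn(par)))
    }
    # iterated Nelder-Mead: re-launching from the endpoint with a fresh
    # simplex recovers from premature simplex collapse
    p <- p0
    val <- Inf
    for (round in seq_len(rounds)) {
      o <- stats::optim(p, wrap, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
      p <- o$par
      if (is.finite(val) && o$value > (1 - 1e-6) * val) { val <- min(val, o$value); break }
      val <- o$value
    }
    par <- pmin(pmax(p, lower), upper)
    list(par = par, value = fn(par))
  }
  starts <- lapply(seq_len(n_restarts), function(r)
    lower + stats::runif(d) * rng)
  starts <- c(starts, extra_starts)
  per <- lapply(starts, function(p0)
    tryCatch(run_one(pmin(pmax(p0, lower), upper)), error = function(e) NULL))
  ok <- !vapply(per, is.null, logical(1))
  if (!any(ok)) stop("all optimizer restarts failed")
  per <- per[ok]
  vals <- vapply(per, `[[`, numeric(1), "value")
  best <- per[[which.min(vals)]]
  if (polish && d > 1) {
    pol <- tryCatch(run_one(best$par), error = function(e) NULL)
    if (!is.null(pol) && pol$value < best$value) best <- pol
  }
  at_bound <- best$par <= lower + 1e-3 * rng | best$par >= upper - 1e-3 * rng
  list(par = best$par, value = best$value, per_restart = per,
       at_bound = at_bound, n_restarts = n_restarts)
}
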