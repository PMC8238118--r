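# log of the square-scheme bracket 1 + [H+]/Ka1 + [H+]^2/(Ka2 Ka1),
# evaluated in the log domain so extreme pKa trial values cannot overflow.
# pKa1 is the dissociation exponent of the singly protonated species,
# pKa2 that of the doubly protonated species.
log_bracket <- function(pH, pKa1, pKa2) {
  l10 <- log(10)
  a <- l10 * (pKa1 - pH)
  b <- l10 * (pKa1 + pKa2 - 2 * pH)
  m <- pmax(0, pmax(a, b))
  m + log(exp(-m) + exp(a - m) + exp(b - m))
}

#' Square-scheme parameters
#'
#' The nine-member square scheme of a two-electron, two-proton couple links
#' three redox levels (oxidized P, one-electron intermediate, fully reduced)
#' each with up to two protonations. `E10`, `E20` are the reversible
#' potentials of the two electron transfers at the alkaline limit (all
#' species deprotonated); the six acid-dissociation exponents are `pKaA`,
#' `pKaB` (doubly/singly protonated oxidized level), `pKaC`, `pKaD`
#' (intermediate level) and `pKaE`, `pKaF` (fully reduced level). `sigE1`,
#' `sigE2` are Gaussian noise scales on the two observed apparent potentials.
#'
#' @param E10,E20 alkaline-limit reversible potentials (V).
#' @param pKaA,pKaB,pKaC,pKaD,pKaE,pKaF acid-dissociation exponents.
#' @param sigE1,sigE2 noise standard deviations (V), `> 0`.
#' @return an object of class `"square_scheme_params"`.
#' @export
square_scheme_params <- function(E10, E20, pKaA, pKaB, pKaC, pKaD, pKaE,
                                 pKaF, sigE1 = 0.002, sigE2 = 0.002) {
  p <- list(E10 = E10, E20 = E20, pKaA = pKaA, pKaB = pKaB, pKaC = pKaC,
            pKaD = pKaD, pKaE = pKaE, pKaF = pKaF, sigE1 = sigE1,
            sigE2 = sigE2)
  stopifnot(all(vapply(p, is.finite, logical(1))), sigE1 > 0, sigE2 > 0)
  structure(p, class = "square_scheme_params")
}

#' Apparent potentials of the square scheme
#'
#' First electron transfer:
#' \deqn{E_{app,1} = E_1^0 - \frac{RT}{F}\ln\frac{1 + [H^+]/K_{aB} +
#'   [H^+]^2/(K_{aA}K_{aB})}{1 + [H^+]/K_{aD} + [H^+]^2/(K_{aC}K_{aD})}}
#' and second electron transfer:
#' \deqn{E_{app,2} = E_2^0 - \frac{RT}{F}\ln\frac{1 + [H^+]/K_{aD} +
#'   [H^+]^2/(K_{aC}K_{aD})}{1 + [H^+]/K_{aF} + [H^+]^2/(K_{aE}K_{aF})}}
#' with \eqn{[H^+] = 10^{-pH}}. Evaluation is carried out in the log domain
#' so extreme pKa values cannot overflow. In pure regimes the slopes
#' approach 0, -59.2 or -118.4 mV per pH unit (at 298.15 K).
#'
#' @param pH solution pH, vectorized.
#' @param p a [square_scheme_params()].
#' @param temperature temperature (K).
#' @return apparent potential (V).
#' @export
eapp1_model <- function(pH, p, temperature = 298.15) {
  stopifnot(inherits(p, "square_scheme_params"), temperature > 0)
  rtf <- .GAS_R * temperature / .FARADAY
  p$E10 - rtf * (log_bracket(pH, p$pKaB, p$pKaA) -
                 log_bracket(pH, p$pKaD, p$pKaC))
}

#' @rdname eapp1_model
#' @export
eapp2_model <- function(pH, p, temperature = 298.15) {
  stopifnot(inherits(p, "square_scheme_params"), temperature > 0)
  rtf <- .GAS_R * temperature / .FARADAY
  p$E20 - rtf * (log_bracket(pH, p$pKaD, p$pKaC) -
                 log_bracket(pH, p$pKaF, p$pKaE))
}

#' Apparent-potential versus pH observations
#'
#' @param pH numeric pH values.
#' @param Eapp1,Eapp2 observed apparent potentials (V).
#' @param experiment experiment identifier per record.
#' @return a `"pourbaix_data"` data frame.
#' @export
pourbaix_data <- function(pH, Eapp1, Eapp2, experiment = seq_along(pH)) {
  stopifnot(all(is.finite(pH)), length(Eapp1) == length(pH),
            length(Eapp2) == length(pH))
  if (length(unique(pH)) < 2)
    stop("at least 2 distinct pH values are required for fitting")
  structure(data.frame(pH = pH, Eapp1_V = Eapp1, Eapp2_V = Eapp2,
                       experiment = experiment),
            class = c("pourbaix_data", "data.frame"))
}

# joint Gaussian log likelihood of all (Eapp1, Eapp2) observations
square_scheme_loglik <- function(p, data, temperature = 298.15) {
  m1 <- eapp1_model(data$pH, p, temperature)
  m2 <- eapp2_model(data$pH, p, temperature)
  sum(stats::dnorm(data$Eapp1_V, m1, p$sigE1, log = TRUE)) +
    sum(stats::dnorm(data$Eapp2_V, m2, p$sigE2, log = TRUE))
}

#' Maximum-likelihood square-scheme fit of Eapp versus pH
#'
#' Maximizes the joint Gaussian log likelihood of all `(Eapp1, Eapp2)`
#' observations under the square-scheme apparent-potential model, with
#' independent noise scales on the two potentials. The noise scales are
#' profiled out analytically (their conditional maximum-likelihood values
#' are the residual RMS values), leaving a bounded 8-parameter search run
#' from `n_restarts` uniform random start points.
#'
#' Only pKa values inside the observed pH range are well constrained; the
#' summary reports a per-parameter identifiability flag from the profile
#' likelihood (re-optimizing all other parameters on a grid across the
#' bounds, with warm-started continuation): a parameter is flagged
#' identifiable when the region within 2 log-likelihood units of the
#' profile maximum is localized to under a quarter of its bound range.
#'
#' @param data a `"pourbaix_data"` (or data frame with `pH`, `Eapp1_V`,
#'   `Eapp2_V`).
#' @param temperature temperature (K), fixed at 298.15 by default.
#' @param n_restarts optimizer restarts (default 20).
#' @param seed RNG seed.
#' @param bounds named list of `c(lo, hi)` overrides; pKa bounds default to
#'   \[-2, 16\], potentials to \[-0.8, 0.3\] V.
#' @param profile compute the profile-likelihood identifiability flags
#'   (adds a few tens of seconds; `FALSE` leaves them `NA`).
#' @return a `"square_scheme_fit"` with methods `coef`, `print`, `summary`,
#'   `predict`, `fitted`, `residuals`, `logLik`, `simulate` and `plot`.
#' @export
fit_square_scheme <- function(data, temperature = 298.15, n_restarts = 20,
                              seed = NULL, bounds = NULL, profile = TRUE) {
  data <- as_pourbaix_df(data)
  defaults <- list(E10 = c(-0.8, 0.3), E20 = c(-0.8, 0.3),
                   pKaA = c(-2, 16), pKaB = c(-2, 16), pKaC = c(-2, 16),
                   pKaD = c(-2, 16), pKaE = c(-2, 16), pKaF = c(-2, 16))
  if (!is.null(bounds)) defaults[names(bounds)] <- bounds
  lo <- vapply(defaults, `[`, numeric(1), 1)
  hi <- vapply(defaults, `[`, numeric(1), 2)
  rng <- hi - lo
  n <- nrow(data)

  par_to_scheme <- function(par, s1 = 1e-3, s2 = 1e-3)
    square_scheme_params(par[["E10"]], par[["E20"]], par[["pKaA"]],
                         par[["pKaB"]], par[["pKaC"]], par[["pKaD"]],
                         par[["pKaE"]], par[["pKaF"]], s1, s2)
  # negative profiled log likelihood: sigmas at their conditional MLE
  nll <- function(u) {
    par <- stats::setNames(lo + u * rng, names(defaults))
    p <- par_to_scheme(par)
    r1 <- data$Eapp1_V - eapp1_model(data$pH, p, temperature)
    r2 <- data$Eapp2_V - eapp2_model(data$pH, p, temperature)
    s1 <- sqrt(mean(r1^2)); s2 <- sqrt(mean(r2^2))
    if (s1 <= 0 || s2 <= 0) return(-Inf)
    n * log(s1) + n * log(s2)
  }
  opt <- multistart_optim(nll, rep(0, 8), rep(1, 8), n_restarts = n_restarts,
                          seed = seed, maxit = 3000, reltol = 1e-12)
  par <- stats::setNames(lo + opt$par * rng, names(defaults))
  p0 <- par_to_scheme(par)
  r1 <- data$Eapp1_V - eapp1_model(data$pH, p0, temperature)
  r2 <- data$Eapp2_V - eapp2_model(data$pH, p0, temperature)
  s1 <- sqrt(mean(r1^2)); s2 <- sqrt(mean(r2^2))
  params <- square_scheme_params(par[["E10"]], par[["E20"]], par[["pKaA"]],
                                 par[["pKaB"]], par[["pKaC"]], par[["pKaD"]],
                                 par[["pKaE"]], par[["pKaF"]], s1, s2)
  coefs <- c(par, sigE1 = s1, sigE2 = s2)
  ll <- square_scheme_loglik(params, data, temperature)

  # profile-likelihood identifiability: fix one parameter on a grid across
  # its bounds and re-optimize the remaining seven (warm-started
  # continuation from the MLE outwards); parameters whose 2-log-likelihood
  # profile region spans a large fraction of the bounds are unidentified
  # (one-sided ridges, e.g. an alkaline-limit potential trading off
  # against an out-of-range pKa, count as unidentified)
  prof_nll <- function(free_names, fixed_name, fixed_val, u_start) {
    f <- function(u_free) {
      par_f <- stats::setNames(lo[free_names] + u_free * rng[free_names],
                               free_names)
      par_all <- c(par_f, stats::setNames(fixed_val, fixed_name))
      p <- par_to_scheme(par_all)
      r1 <- data$Eapp1_V - eapp1_model(data$pH, p, temperature)
      r2 <- data$Eapp2_V - eapp2_model(data$pH, p, temperature)
      s1 <- sqrt(mean(r1^2)); s2 <- sqrt(mean(r2^2))
      if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0)
        return(1e300)
      v <- n * log(s1) + n * log(s2)
      v + 1e4 * sum(pmax(0, u_free - 1)^2 + pmax(0, -u_free)^2)
    }
    o <- stats::optim(u_start, f, method = "Nelder-Mead",
                      control = list(maxit = 700, reltol = 1e-10))
    list(value = f(pmin(pmax(o$par, 0), 1)),
         par = pmin(pmax(o$par, 0), 1))
  }
  u_mle <- (par - lo) / rng
  profile_width <- if (!profile)
    stats::setNames(rep(NA_real_, 8), names(defaults))
  else vapply(names(defaults), function(nm) {
    free <- setdiff(names(defaults), nm)
    grid <- seq(lo[[nm]], hi[[nm]], length.out = 17)
    ll <- numeric(length(grid))
    # continuation outwards from the grid point nearest the MLE
    i0 <- which.min(abs(grid - par[[nm]]))
    for (dirn in list(i0:length(grid), rev(seq_len(i0)))) {
      u_cur <- u_mle[free]
      for (i in dirn) {
        o <- prof_nll(free, nm, grid[i], u_cur)
        ll[i] <- -o$value
        u_cur <- o$par
      }
    }
    diff(range(grid[ll >= max(ll) - 2]))
  }, numeric(1))

  structure(list(coefficients = coefs, params = params, data = data,
                 temperature = temperature, logLik = ll,
                 objective = opt$value, restarts = n_restarts,
                 per_restart = opt$per_restart,
                 bounds = rbind(lo = lo, hi = hi),
                 at_bound = stats::setNames(opt$at_bound, names(defaults)),
                 profile_width = profile_width,
                 identifiable = profile_width < 0.25 * (hi - lo)),
            class = "square_scheme_fit")
}

as_pourbaix_df <- function(data) {
  if (inherits(data, "pourbaix_data")) return(data)
  stopifnot(is.data.frame(data), all(c("pH", "Eapp1_V", "Eapp2_V") %in%
                                       names(data)))
  data
}

#' @export
print.square_scheme_fit <- function(x, ...) {
  cat("Square-scheme fit:", nrow(x$data), "observations,",
      x$restarts, "restarts\n")
  cat("log-likelihood:", format(x$logLik, digits = 7), "\n")
  co <- signif(coef(x), 4)
  flag <- c(ifelse(!is.na(x$identifiable) & !x$identifiable,
                   " (unconstrained)", ""), "", "")
  for (i in seq_along(co))
    cat("  ", format(names(co)[i], width = 6), co[i], flag[i], "\n")
  invisible(x)
}

#' @export
coef.square_scheme_fit <- function(object, ...) object$coefficients

#' @export
logLik.square_scheme_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = 2 * nrow(object$data), class = "logLik")
}

#' @export
predict.square_scheme_fit <- function(object, newdata = NULL, ...) {
  pH <- if (is.null(newdata)) object$data$pH else newdata$pH
  cbind(pH = pH,
        Eapp1_V = eapp1_model(pH, object$params, object$temperature),
        Eapp2_V = eapp2_model(pH, object$params, object$temperature))
}

#' @export
fitted.square_scheme_fit <- function(object, ...) {
  predict(object)[, c("Eapp1_V", "Eapp2_V")]
}

#' @export
residuals.square_scheme_fit <- function(object, ...) {
  f <- fitted(object)
  cbind(Eapp1_V = object$data$Eapp1_V - f[, "Eapp1_V"],
        Eapp2_V = object$data$Eapp2_V - f[, "Eapp2_V"])
}

#' @export
summary.square_scheme_fit <- function(object, ...) {
  print(object)
  cat("\nWidth of the 2-log-likelihood profile region per parameter:\n")
  print(signif(object$profile_width, 3))
  unid <- names(object$identifiable)[!is.na(object$identifiable) &
                                        !object$identifiable]
  cat("Parameters flagged unidentifiable:",
      paste(unid, collapse = ", "), "\n")
  invisible(object)
}

#' @export
simulate.square_scheme_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    m <- predict(object)
    pourbaix_data(object$data$pH,
                  m[, "Eapp1_V"] + stats::rnorm(nrow(m), 0, object$params$sigE1),
                  m[, "Eapp2_V"] + stats::rnorm(nrow(m), 0, object$params$sigE2),
                  object$data$experiment)
  })
}

#' @export
plot.square_scheme_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(min(d$pH) - 0.5, max(d$pH) + 0.5, length.out = 200)
  m <- predict(x, data.frame(pH = grid))
  ylim <- range(d$Eapp1_V, d$Eapp2_V, m[, -1]) * 1e3
  graphics::plot(d$pH, d$Eapp1_V * 1e3, pch = 15, ylim = ylim,
                 xlab = "pH", ylab = "E_app / mV", ...)
  graphics::points(d$pH, d$Eapp2_V * 1e3, pch = 16, col = 2)
  graphics::lines(grid, m[, "Eapp1_V"] * 1e3)
  graphics::lines(grid, m[, "Eapp2_V"] * 1e3, col = 2)
  for (nm in c("pKaD", "pKaE", "pKaF"))
    if (isTRUE(x$identifiable[[nm]]))
      graphics::abline(v = x$coefficients[[nm]], lty = 3, col = "grey40")
  graphics::legend("topright", c("Eapp1", "Eapp2"), pch = c(15, 16),
                   col = c(1, 2), bty = "n")
  invisible(x)
}

#' Pourbaix summary of a fitted square scheme
#'
#' For each pH on the grid: the predicted apparent potentials, the dominant
#' protonation state of each redox level (whichever bracket term dominates),
#' and the implied path segment through the square scheme (how many protons
#' accompany each of the two electron transfers).
#'
#' @param p a [square_scheme_params()] (or a `"square_scheme_fit"`).
#' @param pH_grid numeric grid of pH values.
#' @param temperature temperature (K).
#' @return data frame with one row per grid pH.
#' @export
pourbaix_summary <- function(p, pH_grid, temperature = 298.15) {
  if (inherits(p, "square_scheme_fit")) p <- p$params
  stopifnot(inherits(p, "square_scheme_params"))
  dominant <- function(pH, pKa1, pKa2) {
    l10 <- log(10)
    terms <- cbind(0, l10 * (pKa1 - pH), l10 * (pKa1 + pKa2 - 2 * pH))
    c("deprotonated", "singly-protonated", "doubly-protonated")[
      apply(terms, 1, which.max)]
  }
  protons <- function(state) match(state, c("deprotonated",
                                            "singly-protonated",
                                            "doubly-protonated")) - 1L
  ox <- dominant(pH_grid, p$pKaB, p$pKaA)
  int <- dominant(pH_grid, p$pKaD, p$pKaC)
  red <- dominant(pH_grid, p$pKaF, p$pKaE)
  data.frame(pH = pH_grid,
             Eapp1_V = eapp1_model(pH_grid, p, temperature),
             Eapp2_V = eapp2_model(pH_grid, p, temperature),
             state_oxidized = ox, state_intermediate = int,
             state_reduced = red,
             protons_step1 = protons(int) - protons(ox),
             protons_step2 = protons(red) - protons(int))
}

#' Trend summary of apparent potentials versus pH
#'
#' Arithmetic and regression summaries of an Eapp-versus-pH table: the
#' acidic-branch slope (least-squares over `pH <= acid_max`, both
#' potentials pooled), the mean `Eapp2 - Eapp1` separation on the acidic and
#' alkaline branches, and the total span of apparent potentials.
#'
#' @param data a `"pourbaix_data"`.
#' @param acid_max upper pH of the acidic branch (default 6).
#' @param alk_min lower pH of the alkaline branch (default 7).
#' @return named list: `slope_acidic_mV_per_pH`, `sep_acidic_mV`,
#'   `sep_alkaline_mV`, `span_mV`.
#' @export
eapp_trend_summary <- function(data, acid_max = 6, alk_min = 7) {
  data <- as_pourbaix_df(data)
  acid <- data[data$pH <= acid_max, ]
  long <- data.frame(pH = c(acid$pH, acid$pH),
                     E = c(acid$Eapp1_V, acid$Eapp2_V) * 1e3)
  slope <- unname(stats::coef(stats::lm(E ~ pH, long))["pH"])
  sep <- (data$Eapp2_V - data$Eapp1_V) * 1e3
  list(slope_acidic_mV_per_pH = slope,
       sep_acidic_mV = mean(sep[data$pH <= acid_max]),
       sep_alkaline_mV = mean(sep[data$pH >= alk_min]),
       span_mV = diff(range(c(data$Eapp1_V, data$Eapp2_V))) * 1e3)
}
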