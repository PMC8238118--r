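#' Adaptive Metropolis posterior sampling for the square scheme
#'
#' Samples the posterior of all square-scheme parameters (two alkaline-limit
#' potentials, six pKa values, two noise scales) under the Gaussian
#' likelihood with flat priors inside the bounds (noise scales sampled on
#' the log scale, flat in log). The proposal is Haario-style adaptive
#' Metropolis: after an initial period the proposal covariance is the
#' scaled running sample covariance `(2.4^2 / d) (Cov + eps I)`.
#'
#' pKa values outside the observed pH range are prior-dominated and return
#' wide posteriors; the potential-scale-reduction diagnostic (split-chain
#' R-hat) is computed per parameter and a warning is raised above 1.05.
#'
#' @param data a `"pourbaix_data"`.
#' @param start a `"square_scheme_fit"` or `"square_scheme_params"` giving
#'   the chain start point.
#' @param n_iter iterations per chain.
#' @param n_chains number of chains (`>= 2`, needed for R-hat).
#' @param seed RNG seed; chain `c` uses `seed + c - 1`.
#' @param bounds named list of `c(lo, hi)` prior-support overrides.
#' @param temperature temperature (K).
#' @param burn_in fraction of each chain discarded (default 0.5).
#' @return a `"square_scheme_mcmc"`: post-burn-in samples per chain,
#'   acceptance rates, split R-hat, posterior means/sd and 95% credible
#'   intervals.
#' @export
sample_posterior <- function(data, start, n_iter = 20000, n_chains = 3,
                             seed = NULL, bounds = NULL,
                             temperature = 298.15, burn_in = 0.5) {
  data <- as_pourbaix_df(data)
  if (n_chains < 2) stop("'n_chains' must be >= 2")
  if (inherits(start, "square_scheme_fit")) start <- start$params
  stopifnot(inherits(start, "square_scheme_params"))

  pn <- c("E10", "E20", "pKaA", "pKaB", "pKaC", "pKaD", "pKaE", "pKaF",
          "log_sigE1", "log_sigE2")
  defaults <- list(E10 = c(-0.8, 0.3), E20 = c(-0.8, 0.3),
                   pKaA = c(-2, 16), pKaB = c(-2, 16), pKaC = c(-2, 16),
                   pKaD = c(-2, 16), pKaE = c(-2, 16), pKaF = c(-2, 16),
                   log_sigE1 = log(c(1e-5, 0.1)),
                   log_sigE2 = log(c(1e-5, 0.1)))
  if (!is.null(bounds)) defaults[names(bounds)] <- bounds
  lo <- vapply(defaults, `[`, numeric(1), 1)
  hi <- vapply(defaults, `[`, numeric(1), 2)
  d <- length(pn)

  lpost <- function(x) {
    if (any(x < lo) || any(x > hi)) return(-Inf)
    p <- square_scheme_params(x[1], x[2], x[3], x[4], x[5], x[6], x[7],
                              x[8], exp(x[9]), exp(x[10]))
    square_scheme_loglik(p, data, temperature)
  }
  x0 <- c(start$E10, start$E20, start$pKaA, start$pKaB, start$pKaC,
          start$pKaD, start$pKaE, start$pKaF, log(start$sigE1),
          log(start$sigE2))
  x0 <- pmin(pmax(x0, lo + 1e-9 * (hi - lo)), hi - 1e-9 * (hi - lo))

  sd0 <- 0.005 * (hi - lo)
  adapt_start <- 200L
  eps <- 1e-10
  scale <- 2.4^2 / d

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    x <- x0 + stats::rnorm(d, 0, sd0)
    x <- pmin(pmax(x, lo), hi)
    lp <- lpost(x)
    out <- matrix(NA_real_, n_iter, d)
    acc <- 0L
    mu <- x
    M2 <- matrix(0, d, d)  # running scatter for the sample covariance
    chol_prop <- diag(sd0)
    for (i in seq_len(n_iter)) {
      prop <- x + as.numeric(chol_prop %*% stats::rnorm(d))
      lpp <- lpost(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
        x <- prop; lp <- lpp; acc <- acc + 1L
      }
      out[i, ] <- x
      delta <- x - mu
      mu <- mu + delta / i
      M2 <- M2 + outer(delta, x - mu)
      if (i >= adapt_start && i %% 50 == 0) {
        cv <- scale * (M2 / (i - 1) + eps * diag(d))
        ch <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- t(ch)
      }
    }
    colnames(out) <- pn
    list(samples = out, acceptance = acc / n_iter)
  }

  base_seed <- if (is.null(seed)) sample.int(1e6, 1) else seed
  chains <- lapply(seq_len(n_chains), function(cidx)
    run_chain(base_seed + cidx - 1L))
  keep <- seq.int(floor(n_iter * burn_in) + 1L, n_iter)
  post <- lapply(chains, function(ch) ch$samples[keep, , drop = FALSE])

  rhat <- vapply(seq_len(d), function(j) {
    halves <- do.call(c, lapply(post, function(m) {
      v <- m[, j]
      h <- floor(length(v) / 2)
      list(v[seq_len(h)], v[h + seq_len(h)])
    }))
    nseq <- length(halves)
    nlen <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- nlen * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((nlen - 1) / nlen * W + B / nlen) / W)
  }, numeric(1))
  names(rhat) <- pn
  if (any(rhat > 1.05))
    warning("split R-hat above 1.05 for: ",
            paste(sprintf("%s (%.3f)", pn[rhat > 1.05], rhat[rhat > 1.05]),
                  collapse = ", "))

  all_post <- do.call(rbind, post)
  structure(list(chains = post, full_chains = lapply(chains, `[[`, "samples"),
                 acceptance = vapply(chains, `[[`, numeric(1), "acceptance"),
                 rhat = rhat,
                 mean = colMeans(all_post),
                 sd = apply(all_post, 2, stats::sd),
                 ci95 = apply(all_post, 2, stats::quantile,
                              probs = c(0.025, 0.975)),
                 n_iter = n_iter, burn_in = burn_in, seed = base_seed),
            class = "square_scheme_mcmc")
}

#' @export
print.square_scheme_mcmc <- function(x, ...) {
  cat("Adaptive Metropolis posterior:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "post-burn-in draws\n")
  cat("acceptance:", paste(signif(x$acceptance, 3), collapse = ", "), "\n")
  tab <- cbind(mean = x$mean, sd = x$sd, t(x$ci95), rhat = x$rhat)
  print(signif(tab, 4))
  invisible(x)
}

#' Export posterior chains as CSV
#' @param x a `"square_scheme_mcmc"`.
#' @param path output file; one row per draw with a chain column.
#' @export
write_chains <- function(x, path) {
  d <- do.call(rbind, lapply(seq_along(x$chains), function(i)
    data.frame(chain = i, x$chains[[i]])))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
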