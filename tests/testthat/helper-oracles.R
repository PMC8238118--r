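# shared constants and independent oracles used across test files

FARADAY <- 96485.33212
GAS_R <- 8.31446261815324
RTF <- GAS_R * 298.15 / FARADAY  # 25.693 mV at 298.15 K

# reversible dc surface-wave peak current for n electrons (A); Gamma in mol
reversible_peak <- function(n, v, Gamma, temperature = 298.15) {
  n^2 * FARADAY^2 * v * Gamma / (4 * GAS_R * temperature)
}

# bare cell without background, for Faradaic-only studies
bare_cell <- function(Gamma = 3.5e-12, Ru = 0) {
  cell_parameters(Ru = Ru, S = 0.03, Gamma = Gamma)
}

# full width at half maximum of current-vs-potential data by interpolation
fwhm <- function(E, I) {
  ip <- max(I)
  half <- which(I >= ip / 2)
  abs(E[half[1]] - E[half[length(half)]])
}

# naive O(n^2) discrete Fourier transform (independent of stats::fft)
naive_dft <- function(x) {
  n <- length(x)
  k <- seq_len(n) - 1
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * (seq_len(n) - 1) / n)), complex(1))
}

# local maxima of an envelope above a relative threshold, merged within
# min_sep samples
count_env_peaks <- function(env, thr = 0.05, min_sep = 100) {
  idx <- which(diff(sign(diff(env))) == -2) + 1
  idx <- idx[env[idx] > thr * max(env)]
  if (!length(idx)) return(0L)
  length(idx[c(TRUE, diff(idx) > min_sep)])
}

# equilibrium (Nernst-only) Faradaic current oracle on a trace grid:
# I = F * Gamma * d(thX - thZ)/dt with occupancies from the Nernst equation
nernst_current_oracle <- function(trace, E1, E2, Gamma) {
  occ <- nernst_occupancies(trace$E_applied_V, E1, E2)
  q <- occ[, "thX"] - occ[, "thZ"]
  n <- length(q)
  dt <- trace$t_s[2] - trace$t_s[1]
  c(NA, FARADAY * Gamma * (q[3:n] - q[1:(n - 2)]) / (2 * dt), NA)
}

# joint Gaussian log likelihood of a pourbaix table under given parameters
# (independent re-computation used to check fit/MCMC outputs)
pourbaix_loglik <- function(p, data, temperature = 298.15) {
  sum(stats::dnorm(data$Eapp1_V, eapp1_model(data$pH, p, temperature),
                   p$sigE1, log = TRUE)) +
    sum(stats::dnorm(data$Eapp2_V, eapp2_model(data$pH, p, temperature),
                     p$sigE2, log = TRUE))
}

# square-scheme truth used by the synthetic recovery studies: all three
# alkaline-side pKas (D, E, F) inside the observed pH range so the
# potentials and those pKas are identifiable from an 18-record table
recovery_truth <- function() {
  square_scheme_params(E10 = -0.30, E20 = -0.35, pKaA = 1, pKaB = 2,
                       pKaC = 2.5, pKaD = 7.0, pKaE = 5.5, pKaF = 8.5,
                       sigE1 = 0.002, sigE2 = 0.002)
}
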