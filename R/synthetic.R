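#' Study-condition presets
#'
#' `study_waveform()` reproduces the experimental FTACV settings emulated by
#' the synthetic-data generator: dc scan rate 22.4 mV s^-1, sine amplitude
#' 150 mV, frequency 8.96 Hz, with a dc window wide enough to cover the
#' apparent potentials observed between pH 4 and 9. `study_cell()` supplies
#' matching cell constants: 0.03 cm^2 electrode, ~3.5 pmol coverage, an
#' uncompensated resistance in the fitted 9-120 Ohm range, and a dual cubic
#' capacitance polynomial of the magnitude typical of a pyrolytic graphite
#' edge electrode (about 100 uF cm^-2 with mild potential dependence).
#'
#' @param E_start,E_reverse dc window (V); default 0.05 to -0.45 V.
#' @param samples_per_period output samples per ac period.
#' @param Ru,Gamma,cap_forward,cap_reverse see [cell_parameters()].
#' @return a [waveform_spec()] / [cell_parameters()].
#' @export
study_waveform <- function(E_start = 0.05, E_reverse = -0.45,
                           samples_per_period = 400) {
  waveform_spec(E_start, E_reverse, v = 0.0224, dE = 0.150, f = 8.96,
                eta = 0, samples_per_period = samples_per_period)
}

#' @rdname study_waveform
#' @export
study_cell <- function(Ru = 27, Gamma = 3.5e-12,
                       cap_forward = c(1.2e-4, 0.15, -0.20, 0.10),
                       cap_reverse = c(1.0e-4, 0.12, -0.15, 0.08)) {
  cell_parameters(Ru = Ru, temperature = 298.15, S = 0.03, Gamma = Gamma,
                  cap_forward = cap_forward, cap_reverse = cap_reverse)
}

#' Ground-truth record for synthetic data
#'
#' Bundles everything needed to regenerate a synthetic dataset
#' bit-identically: the mechanism tag, its parameters, the cell and
#' waveform (or square-scheme parameters), the noise level and the seed.
#'
#' @param model_tag `"sequential"`, `"concerted"` or `"square_scheme"`.
#' @param params a `sequential_params`/`concerted_params` or
#'   `square_scheme_params` object.
#' @param cell,waveform cell and waveform for trace generation (ignored for
#'   `"square_scheme"`).
#' @param noise_sd additive Gaussian noise sd on the total current (A); if
#'   `NULL`, set from `snr`.
#' @param snr target ratio of the fundamental-harmonic envelope peak to the
#'   noise sd, used when `noise_sd` is `NULL` (default 100, at which nine
#'   and more harmonics stay resolvable).
#' @param seed RNG seed stored with the truth.
#' @return a `"synthetic_truth"` list.
#' @export
ftacv_truth <- function(model_tag = c("sequential", "concerted",
                                      "square_scheme"),
                        params, cell = study_cell(),
                        waveform = study_waveform(), noise_sd = NULL,
                        snr = 100, seed = 1L) {
  model_tag <- match.arg(model_tag)
  structure(list(model_tag = model_tag, params = params, cell = cell,
                 waveform = waveform, noise_sd = noise_sd, snr = snr,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a synthetic FTACV trace with known truth
#'
#' Simulates the trace for the truth's mechanism and adds i.i.d. Gaussian
#' noise to the total current. When `noise_sd` is unset it is derived from
#' the target `snr` as (fundamental-harmonic envelope peak) / snr and the
#' realized value is recorded in the returned truth. The noise-free
#' component columns are retained alongside the noisy `I_total_A`.
#'
#' @param truth a [ftacv_truth()] with a trace mechanism.
#' @param n_sub simulator substeps.
#' @return list with elements `trace` (an `"ftacv_trace"`) and `truth` (the
#'   input truth with `noise_sd` filled in).
#' @export
generate_ftacv <- function(truth, n_sub = 4) {
  stopifnot(inherits(truth, "synthetic_truth"),
            truth$model_tag %in% c("sequential", "concerted"))
  tr <- if (truth$model_tag == "sequential")
    simulate_sequential(truth$params, truth$cell, truth$waveform,
                        n_sub = n_sub)
  else
    simulate_concerted(truth$params, truth$cell, truth$waveform,
                       n_sub = n_sub)
  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) {
    h1 <- extract_harmonics(tr, orders = 1, f = truth$waveform$f)
    noise_sd <- max(h1$envelopes[, 1]) / truth$snr
  }
  truth$noise_sd <- noise_sd
  if (noise_sd > 0) {
    set.seed(truth$seed)
    tr$I_total_A <- tr$I_total_A + stats::rnorm(nrow(tr), 0, noise_sd)
  }
  attr(tr, "truth") <- truth
  list(trace = tr, truth = truth)
}

#' Generate a synthetic Eapp-versus-pH table with known truth
#'
#' Evaluates the square-scheme apparent potentials on the pH grid and adds
#' Gaussian noise `sigE1` / `sigE2` to each record. The default layout is
#' three repeated experiments at each of pH 4-9 (18 records).
#'
#' @param truth a [ftacv_truth()] with `model_tag = "square_scheme"` whose
#'   `params` is a [square_scheme_params()].
#' @param pH_list pH values.
#' @param reps repeated experiments per pH.
#' @param temperature temperature (K).
#' @return list with elements `data` (a `"pourbaix_data"`) and `truth`.
#' @export
generate_pourbaix <- function(truth, pH_list = 4:9, reps = 3,
                              temperature = 298.15) {
  stopifnot(inherits(truth, "synthetic_truth"),
            truth$model_tag == "square_scheme", reps >= 1)
  p <- truth$params
  pH <- rep(pH_list, each = reps)
  m1 <- eapp1_model(pH, p, temperature)
  m2 <- eapp2_model(pH, p, temperature)
  set.seed(truth$seed)
  d <- pourbaix_data(pH,
                     m1 + stats::rnorm(length(pH), 0, p$sigE1),
                     m2 + stats::rnorm(length(pH), 0, p$sigE2),
                     experiment = rep(seq_len(reps), times = length(pH_list)))
  attr(d, "truth") <- truth
  list(data = d, truth = truth)
}
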