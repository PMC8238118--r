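#' Read a pipeline run configuration
#'
#' YAML configuration with sections `waveform`, `cell`, `model`, `fitting`,
#' `mcmc`, `synth`, `square_scheme`, plus top-level `seed` and `output_dir`.
#' Unknown keys are rejected. All omitted values fall back to the function
#' defaults of the corresponding stage.
#'
#' @param path YAML file path.
#' @return a validated `"run_config"` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("waveform", "cell", "model", "fitting", "mcmc", "synth",
             "square_scheme", "seed", "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  attr(cfg, "path") <- path
  class(cfg) <- "run_config"
  cfg
}

cfg_call <- function(f, args) do.call(f, args[!vapply(args, is.null, TRUE)])

#' Run the full analysis pipeline
#'
#' Executes the stages of the two-step analysis in order on a synthetic or
#' loaded dataset: trace generation (or loading), the time-domain
#' capacitance/resistance fit, the Fourier-domain Faradaic fits under both
#' mechanisms with comparison, harmonic extraction, and (when an
#' Eapp-versus-pH table is configured) the square-scheme fit. Results are
#' written to `output_dir` as JSON/CSV together with a provenance log
#' recording the configuration hash, seed and package version.
#'
#' @param config a `"run_config"` from [read_run_config()].
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$synth) || !is.null(config$model)) {
    wf_args <- list(E_start = 0.05, E_reverse = -0.45, v = 0.0224,
                    dE = 0.150, f = 8.96, eta = 0, samples_per_period = 400)
    extra_wf <- setdiff(names(config$waveform), names(wf_args))
    if (length(extra_wf))
      stop("unknown waveform keys: ", paste(extra_wf, collapse = ", "))
    wf_args[names(config$waveform)] <- config$waveform
    wv <- stage("waveform", do.call(waveform_spec, wf_args))
    cell_args <- lapply(config$cell, function(x)
      if (is.list(x)) unlist(x) else x)
    cl <- stage("cell", cfg_call(study_cell, cell_args))
    mdl <- config$model
    if (is.null(mdl)) mdl <- list(tag = "sequential", E1 = -0.215,
                                  E2 = -0.206, k1 = 4000, k2 = 4000)
    pars <- if (identical(mdl$tag, "concerted"))
      concerted_params(mdl$E3, mdl$k3)
    else sequential_params(mdl$E1, mdl$E2, mdl$k1, mdl$k2)
    truth <- ftacv_truth(if (identical(mdl$tag, "concerted")) "concerted"
                         else "sequential",
                         pars, cl, wv,
                         noise_sd = config$synth$noise_sd,
                         snr = if (is.null(config$synth$snr)) 100
                               else config$synth$snr,
                         seed = seed)
    gen <- stage("synth", generate_ftacv(truth))
    results$trace <- gen$trace
    write_trace(gen$trace, file.path(out_dir, "trace.csv"))

    fit_args <- config$fitting
    nr <- if (is.null(fit_args$restarts)) 10 else fit_args$restarts
    span <- abs(wv$E_start - wv$E_reverse)
    hw <- if (!is.null(fit_args$half_window)) fit_args$half_window
          else min(0.2, 0.4 * span)
    cap <- stage("fit-capacitance", fit_capacitance(
      gen$trace, select_nonfaradaic_regions(gen$trace, half_window = hw),
      n_restarts = nr, seed = seed))
    write_fit(cap, file.path(out_dir, "capacitance_fit.json"))
    cmp <- stage("compare-models",
                 compare_models(gen$trace, cap, n_restarts = nr,
                                seed = seed + 1L,
                                maxit = if (is.null(fit_args$maxit)) 1200
                                        else fit_args$maxit))
    write_fit(cmp, file.path(out_dir, "model_comparison.json"))
    results$capacitance <- cap
    results$comparison <- cmp
    hs <- stage("harmonics", extract_harmonics(gen$trace))
    write_harmonics(hs, wv, file.path(out_dir, "harmonics.csv"))
    results$harmonics <- hs
  }

  if (!is.null(config$square_scheme)) {
    sq <- config$square_scheme
    dat <- stage("square-scheme-data",
                 if (!is.null(sq$data)) read_pourbaix(sq$data)
                 else hypd_table1("pourbaix"))
    nr <- if (is.null(sq$restarts)) 20 else sq$restarts
    fit <- stage("pourbaix-fit",
                 fit_square_scheme(dat, n_restarts = nr, seed = seed,
                                   profile = isTRUE(sq$profile)))
    results$square_scheme <- fit
    jsonlite::write_json(as.list(coef(fit)),
                         file.path(out_dir, "square_scheme_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(config$mcmc)) {
      mc <- stage("pourbaix-mcmc", sample_posterior(
        dat, fit,
        n_iter = if (is.null(config$mcmc$iters)) 20000 else config$mcmc$iters,
        n_chains = if (is.null(config$mcmc$chains)) 3 else config$mcmc$chains,
        seed = seed))
      write_chains(mc, file.path(out_dir, "square_scheme_chains.csv"))
      results$mcmc <- mc
    }
  }

  prov <- list(config = attr(config, "path"),
               config_md5 = unname(tools::md5sum(attr(config, "path"))),
               seed = seed,
               package_version = as.character(utils::packageVersion("ftacv")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
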