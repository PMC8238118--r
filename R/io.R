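#' Read and write current traces
#'
#' Traces are stored as comma-separated text with '.' decimal and a
#' mandatory header. The full layout has columns `t_s`, `E_applied_V`,
#' `E_effective_V`, `I_total_A`, `I_faradaic_A`, `I_capacitive_A`,
#' `dc_direction`; experimental exports with only three columns
#' (time, applied potential, total current) are accepted, in which case the
#' component-current columns are absent.
#'
#' @param path file path.
#' @param waveform optional [waveform_spec()] to attach to the loaded trace
#'   (needed for harmonic extraction and fitting).
#' @param cell optional [cell_parameters()] to attach.
#' @return `read_trace()`: an `"ftacv_trace"`; `write_trace()`: the path,
#'   invisibly.
#' @export
read_trace <- function(path, waveform = NULL, cell = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  full <- c("t_s", "E_applied_V", "I_total_A")
  if (all(full %in% names(d))) {
    tr <- d
  } else if (ncol(d) == 3) {
    names(d) <- full
    tr <- d
  } else {
    stop("malformed header: expected columns ", paste(full, collapse = ", "),
         " or a plain 3-column (t, E, I) file")
  }
  if (any(diff(tr$t_s) <= 0)) stop("non-monotone time column")
  structure(tr, class = c("ftacv_trace", "data.frame"),
            waveform = waveform, cell = cell)
}

#' @rdname read_trace
#' @param trace an `"ftacv_trace"`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read and write Eapp-versus-pH tables
#'
#' CSV layout: `pH`, `Eapp1_mV`, `Eapp2_mV`, `experiment` (potentials in mV
#' in the file, volts in memory).
#'
#' @param path file path.
#' @return `read_pourbaix()`: a `"pourbaix_data"`.
#' @export
read_pourbaix <- function(path) {
  d <- utils::read.csv(path)
  need <- c("pH", "Eapp1_mV", "Eapp2_mV")
  if (!all(need %in% names(d)))
    stop("malformed header: expected columns ", paste(need, collapse = ", "))
  pourbaix_data(d$pH, d$Eapp1_mV / 1e3, d$Eapp2_mV / 1e3,
                if ("experiment" %in% names(d)) d$experiment
                else seq_len(nrow(d)))
}

#' @rdname read_pourbaix
#' @param data a `"pourbaix_data"`.
#' @export
write_pourbaix <- function(data, path) {
  d <- data.frame(pH = data$pH, Eapp1_mV = data$Eapp1_V * 1e3,
                  Eapp2_mV = data$Eapp2_V * 1e3,
                  experiment = data$experiment)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Best-fit apparent potentials of HypD versus pH
#'
#' The packaged table of best-fit parameter values for the two-sequential
#' one-electron transfer model of *E. coli* HypD FTACV: three repeated
#' experiments at each of pH 4.0-9.0, with rate constants (s^-1), apparent
#' potentials (mV vs. SHE), phase, per-area coverage and the Fourier-domain
#' objective value of each fit. This printed table is the input to the
#' square-scheme (Pourbaix) stage.
#'
#' @param as `"table"` for the full table, `"pourbaix"` for a
#'   `"pourbaix_data"` of (pH, Eapp1, Eapp2, experiment) in volts.
#' @return data frame (see `as`).
#' @export
hypd_table1 <- function(as = c("pourbaix", "table")) {
  as <- match.arg(as)
  path <- system.file("extdata", "hypd_table1.csv", package = "ftacv",
                      mustWork = TRUE)
  d <- utils::read.csv(path)
  if (as == "table") return(d)
  pourbaix_data(d$pH, d$Eapp1_mV / 1e3, d$Eapp2_mV / 1e3, d$experiment)
}
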