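#' Electrode and cell constants
#'
#' Collects the non-Faradaic constants of the electrochemical cell: the
#' uncompensated resistance `Ru` (giving the Ohmic drop `E_eff = E_app - Ru *
#' I_total`), temperature, electrode area, total electroactive coverage and a
#' dual cubic-polynomial double-layer capacitance model with separate
#' coefficient sets for the forward (first) and reverse dc sweeps.
#'
#' The capacitance per unit area at effective potential `E` is
#' `c0 * (1 + c1 E + c2 E^2 + c3 E^3)` (F cm^-2) with the coefficient set
#' matching the current dc sweep direction.
#'
#' @param Ru uncompensated resistance (Ohm), `>= 0`.
#' @param temperature temperature (K).
#' @param S electrode area (cm^2); 0.03 cm^2 for the pyrolytic graphite tip
#'   emulated by the study preset.
#' @param Gamma total electroactive coverage (mol). Per-area coverage is
#'   `Gamma / S`.
#' @param cap_forward,cap_reverse numeric length-4 coefficient vectors
#'   `c(c0, c1, c2, c3)`; `c0` in F cm^-2, `c1..c3` per V, V^2, V^3.
#'   `cap_reverse` defaults to `cap_forward`.
#' @return An object of class `"cell_parameters"`.
#' @export
cell_parameters <- function(Ru = 0, temperature = 298.15, S = 0.03,
                            Gamma = 3.5e-12,
                            cap_forward = c(0, 0, 0, 0),
                            cap_reverse = cap_forward) {
  stopifnot(length(cap_forward) == 4, length(cap_reverse) == 4,
            is.finite(Ru), is.finite(temperature), is.finite(S),
            is.finite(Gamma), all(is.finite(cap_forward)),
            all(is.finite(cap_reverse)))
  if (Ru < 0) stop("'Ru' must be >= 0")
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (S <= 0) stop("'S' must be > 0")
  if (Gamma < 0) stop("'Gamma' must be >= 0")
  if (cap_forward[1] < 0 || cap_reverse[1] < 0)
    stop("leading capacitance coefficient c0 must be >= 0")
  structure(list(Ru = Ru, temperature = temperature, S = S, Gamma = Gamma,
                 cap_forward = as.numeric(cap_forward),
                 cap_reverse = as.numeric(cap_reverse)),
            class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("Cell: Ru =", x$Ru, "Ohm, T =", x$temperature, "K, S =", x$S,
      "cm^2, Gamma =", format(x$Gamma / 1e-12), "pmol\n")
  cat("  Cdl forward:", paste(signif(x$cap_forward, 4), collapse = ", "), "\n")
  cat("  Cdl reverse:", paste(signif(x$cap_reverse, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Capacitive (double-layer charging) current
#'
#' `S * c0 * (1 + c1 E + c2 E^2 + c3 E^3) * dEdt` with the coefficient set for
#' the given dc sweep direction. A polynomial that goes negative inside the
#' potential window is physically meaningless; it is clamped at zero with a
#' warning.
#'
#' @param E_eff effective (post-Ohmic-drop) potential (V), vectorized.
#' @param dEdt time derivative of the applied potential (V s^-1).
#' @param direction `"forward"` or `"reverse"`, selecting the coefficient set.
#' @param cell a [cell_parameters()].
#' @return capacitive current (A).
#' @export
capacitive_current <- function(E_eff, dEdt, direction = c("forward", "reverse"),
                               cell) {
  direction <- match.arg(direction)
  stopifnot(inherits(cell, "cell_parameters"))
  cc <- if (direction == "forward") cell$cap_forward else cell$cap_reverse
  p <- 1 + E_eff * (cc[2] + E_eff * (cc[3] + E_eff * cc[4]))
  if (any(p < 0)) {
    warning("capacitance polynomial negative inside the potential window; clamped at 0")
    p <- pmax(p, 0)
  }
  cell$S * cc[1] * p * dEdt
}
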