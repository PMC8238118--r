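#' Faradaic reaction parameters
#'
#' `sequential_params()` describes two stepwise one-electron transfers
#' (oxidized X -> intermediate Y -> fully reduced Z), each with an apparent
#' reversible potential, a rate constant at that potential, and a transfer
#' coefficient. `concerted_params()` describes a single concerted two-electron
#' transfer X -> Z. Apparent potentials absorb the protonation equilibria of
#' an EC step, so these are the natural parameters for a proton-coupled
#' electron-transfer couple at fixed pH.
#'
#' @param E1,E2,E3 apparent reversible potentials (V).
#' @param k1,k2,k3 rate constants at the respective apparent potential
#'   (s^-1), `>= 0`.
#' @param a1,a2,a3 transfer coefficients, in (0, 1).
#' @return An object of class `"sequential_params"` or `"concerted_params"`.
#' @export
sequential_params <- function(E1, E2, k1, k2, a1 = 0.5, a2 = 0.5) {
  stopifnot(is.finite(E1), is.finite(E2), k1 >= 0, k2 >= 0,
            a1 > 0, a1 < 1, a2 > 0, a2 < 1)
  structure(list(E1 = E1, E2 = E2, k1 = k1, k2 = k2, a1 = a1, a2 = a2),
            class = "sequential_params")
}

#' @rdname sequential_params
#' @export
concerted_params <- function(E3, k3, a3 = 0.5) {
  stopifnot(is.finite(E3), k3 >= 0, a3 > 0, a3 < 1)
  structure(list(E3 = E3, k3 = k3, a3 = a3), class = "concerted_params")
}

#' Butler-Volmer rate constants
#'
#' For an n-electron couple with reversible potential `E0`, rate constant
#' `k0` at `E0` and transfer coefficient `a`:
#' \deqn{k_{red} = k_0 e^{-a n F (E - E_0)/RT}, \quad
#'       k_{ox} = k_0 e^{(1-a) n F (E - E_0)/RT}}
#' so that \eqn{k_{ox}/k_{red} = e^{n F (E - E_0)/RT}} (detailed balance,
#' consistent with the Nernst equation, independent of `a`).
#'
#' @param E electrode potential (V), vectorized.
#' @param E0 reversible potential (V).
#' @param k0 rate constant at `E0` (s^-1).
#' @param a transfer coefficient in (0, 1).
#' @param n number of electrons (1 or 2).
#' @param temperature temperature (K).
#' @return list with components `k_red` and `k_ox` (s^-1).
#' @export
bv_rates <- function(E, E0, k0, a, n = 1, temperature = 298.15) {
  if (any(!is.finite(E))) stop("'E' must be finite")
  stopifnot(k0 >= 0, a > 0, a < 1, n %in% c(1, 2), temperature > 0)
  x <- n * .FARADAY * (E - E0) / (.GAS_R * temperature)
  list(k_red = k0 * exp(-a * x), k_ox = k0 * exp((1 - a) * x))
}

#' Equilibrium occupancies of the three-state sequential couple
#'
#' Nernst-equation populations of oxidized (X), intermediate (Y) and fully
#' reduced (Z) states at potential `E` for two one-electron couples with
#' reversible potentials `E1` (X/Y) and `E2` (Y/Z).
#'
#' @param E potential (V), vectorized.
#' @param E1,E2 reversible potentials of the first and second couple (V).
#' @param temperature temperature (K).
#' @return matrix with columns `thX`, `thY`, `thZ` summing to 1 row-wise.
#' @export
nernst_occupancies <- function(E, E1, E2, temperature = 298.15) {
  stopifnot(temperature > 0, all(is.finite(E)))
  f <- .FARADAY / (.GAS_R * temperature)
  # thX/thY = exp(f (E - E1)); thZ/thY = exp(-f (E - E2)); log-domain
  lx <- f * (E - E1)
  lz <- -f * (E - E2)
  m <- pmax(lx, pmax(0, lz))
  den <- exp(lx - m) + exp(-m) + exp(lz - m)
  cbind(thX = exp(lx - m) / den, thY = exp(-m) / den, thZ = exp(lz - m) / den)
}

#' Equilibrium fraction of the one-electron intermediate
#'
#' \deqn{\theta_Y(E) = 1 / (1 + e^{F(E-E_1)/RT} + e^{-F(E-E_2)/RT})}
#' maximal at the midpoint `E = (E1 + E2) / 2`. With "crossed" potentials
#' (`E2 > E1`, the second electron easier than the first) the maximum stays
#' below 1/3; with normally ordered potentials (`E2 < E1`) the intermediate
#' exceeds 1/3 at the midpoint and dominates once the separation is large.
#'
#' @inheritParams nernst_occupancies
#' @return intermediate fraction in \[0, 1\], vectorized over `E`.
#' @export
nernst_intermediate_fraction <- function(E, E1, E2, temperature = 298.15) {
  unname(nernst_occupancies(E, E1, E2, temperature)[, "thY"])
}
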