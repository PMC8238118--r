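# shared small waveforms: windows chosen so traces stay a few tens of
# thousands of samples
w_dc <- waveform_spec(0.2, -0.2, v = 0.0224, dE = 0, f = 8.96,
                      samples_per_period = 400)
w_ac <- waveform_spec(0.2, -0.2, samples_per_period = 400)

test_that("zero coverage gives a purely capacitive trace", {
  cell <- cell_parameters(Ru = 0, Gamma = 0,
                          cap_forward = c(1e-4, 0.2, -0.1, 0.05),
                          cap_reverse = c(8e-5, 0.1, 0, 0))
  tr <- simulate_sequential(sequential_params(-0.1, 0, 100, 100), cell, w_ac)
  expect_equal(max(abs(tr$I_faradaic_A)), 0)
  # matches the analytic capacitive current at the applied potential (Ru = 0)
  dEdt <- c(diff(tr$E_applied_V)[1], diff(tr$E_applied_V)) /
    (tr$t_s[2] - tr$t_s[1])
  fwd <- tr$dc_direction == "forward"
  icap <- capacitive_current(tr$E_applied_V[fwd], 1, "forward", cell)
  # compare via the analytic rate at sample times
  ww <- w_ac
  rate <- -ww$v + ww$dE * 2 * pi * ww$f * cos(2 * pi * ww$f * tr$t_s[fwd])
  expect_equal(tr$I_total_A[fwd], icap * rate, tolerance = 1e-10)
})

test_that("trace columns satisfy the additivity and Ohmic-drop identities", {
  cell <- cell_parameters(Ru = 50, Gamma = 3.5e-12,
                          cap_forward = c(1.2e-4, 0.15, -0.2, 0.1),
                          cap_reverse = c(1e-4, 0.12, -0.15, 0.08))
  tr <- simulate_sequential(sequential_params(-0.05, 0.0, 500, 800), cell,
                            waveform_spec(0.15, -0.2, samples_per_period = 200),
                            n_sub = 2)
  expect_equal(tr$I_total_A, tr$I_faradaic_A + tr$I_capacitive_A)
  expect_equal(tr$E_effective_V, tr$E_applied_V - 50 * tr$I_total_A)
  occ <- attr(tr, "occupancy")
  expect_true(all(abs(rowSums(occ) - 1) < 1e-6))
  expect_true(all(occ > -1e-6 & occ < 1 + 1e-6))
})

test_that("the reversible dc surface waves match their closed forms", {
  cell <- bare_cell()
  # single one-electron couple (second rate constant zero)
  tr1 <- simulate_sequential(sequential_params(0, 0, 1e5, 0), cell, w_dc)
  keep <- tr1$dc_direction == "forward" & tr1$t_s > 0.5  # drop start-up
  I1 <- -tr1$I_faradaic_A[keep]
  E1 <- tr1$E_applied_V[keep]
  expect_equal(max(I1), reversible_peak(1, 0.0224, 3.5e-12),
               tolerance = 0.01)
  expect_equal(fwhm(E1, I1) * 1e3, 90.6, tolerance = 1 / 90.6)
  # concerted two-electron wave: four times the peak, half the width
  tr2 <- simulate_concerted(concerted_params(0, 1e5), cell, w_dc)
  I2 <- -tr2$I_faradaic_A[keep]
  expect_equal(max(I2), 4 * reversible_peak(1, 0.0224, 3.5e-12),
               tolerance = 0.01)
  expect_equal(fwhm(tr2$E_applied_V[keep], I2) * 1e3, 45.3,
               tolerance = 1 / 45.3)
})

test_that("fast kinetics reproduce the Nernstian equilibrium oracle", {
  cell <- bare_cell()
  tr <- simulate_sequential(sequential_params(-0.05, 0.05, 1e5, 1e5), cell,
                            w_ac, n_sub = 8)
  orc <- nernst_current_oracle(tr, -0.05, 0.05, 3.5e-12)
  keep <- tr$t_s > 0.25 & tr$t_s < max(tr$t_s) - 0.25
  err <- max(abs(orc[keep] - tr$I_faradaic_A[keep])) /
    max(abs(tr$I_faradaic_A[keep]))
  expect_lt(err, 0.01)
})

test_that("the integrator agrees with a stiff ODE solver oracle", {
  # moderate kinetics with capacitive background, Ru = 0
  wk <- waveform_spec(0.1, -0.1, samples_per_period = 200)
  cell <- cell_parameters(Ru = 0, Gamma = 3.5e-12,
                          cap_forward = c(1e-4, 0.1, -0.1, 0.05))
  p <- sequential_params(-0.03, 0.01, 50, 80)
  tr <- simulate_sequential(p, cell, wk, n_sub = 4)
  frt <- FARADAY / (GAS_R * 298.15)
  rhs <- function(t, y, parms) {
    E <- ftacv_potential(t, wk)
    k1r <- 50 * exp(-0.5 * frt * (E + 0.03))
    k1o <- 50 * exp(0.5 * frt * (E + 0.03))
    k2r <- 80 * exp(-0.5 * frt * (E - 0.01))
    k2o <- 80 * exp(0.5 * frt * (E - 0.01))
    thY <- 1 - y[1] - y[2]
    list(c(k1o * thY - k1r * y[1], k2r * thY - k2o * y[2]))
  }
  sol <- deSolve::lsoda(c(1, 0), tr$t_s, rhs, rtol = 1e-8, atol = 1e-10)
  q <- sol[, 2] - sol[, 3]
  n <- nrow(sol)
  dt <- tr$t_s[2]
  iode <- FARADAY * 3.5e-12 * c(NA, (q[3:n] - q[1:(n - 2)]) / (2 * dt), NA)
  ok <- is.finite(iode)
  expect_lt(max(abs(iode[ok] - tr$I_faradaic_A[ok])) /
              max(abs(tr$I_faradaic_A[ok])), 1e-3)
})

test_that("Faradaic charge balances over a closed cycle", {
  cell <- bare_cell()
  tr <- simulate_sequential(sequential_params(-0.02, 0.02, 500, 500), cell,
                            w_dc)
  dt <- tr$t_s[2]
  net <- abs(sum(tr$I_faradaic_A) * dt)
  total <- sum(abs(tr$I_faradaic_A)) * dt
  expect_lt(net / total, 1e-3)
})

test_that("crossed sequential potentials converge to the concerted wave", {
  # E2 = E1 + 200 mV, reversible: RMS deviation from the concerted trace at
  # the midpoint potential is a small fraction of the peak amplitude,
  # while a 25 mV crossing is clearly distinguishable
  cell <- bare_cell()
  trc <- simulate_concerted(concerted_params(0, 1e5), cell, w_ac, n_sub = 8)
  trs <- simulate_sequential(sequential_params(-0.1, 0.1, 1e5, 1e5), cell,
                             w_ac, n_sub = 8)
  keep <- trs$t_s > 0.25 & trs$t_s < max(trs$t_s) - 0.25
  pk <- max(abs(trc$I_faradaic_A[keep]))
  rms200 <- sqrt(mean((trs$I_faradaic_A[keep] - trc$I_faradaic_A[keep])^2))
  expect_lt(rms200 / pk, 0.005)
  trs25 <- simulate_sequential(sequential_params(-0.0125, 0.0125, 1e5, 1e5),
                               cell, w_ac, n_sub = 8)
  rms25 <- sqrt(mean((trs25$I_faradaic_A[keep] - trc$I_faradaic_A[keep])^2))
  expect_gt(rms25 / rms200, 5)
})

test_that("concerted harmonic shapes separate reversible from quasi-reversible", {
  # reversible kinetics: harmonic-6 envelope drops to near zero between
  # peaks; at k3 = 200 s^-1 the inter-peak valleys fill in
  wf <- waveform_spec(0.2, -0.2, v = 0.0224, dE = 0.15, f = 9,
                      samples_per_period = 400)
  cell <- bare_cell()
  valley <- function(k3) {
    tr <- simulate_concerted(concerted_params(0, k3), cell, wf, n_sub = 2)
    hs <- extract_harmonics(tr, orders = 6, current = "I_faradaic_A")
    fwd <- which(tr$dc_direction == "forward" & tr$t_s > 1)
    env <- hs$envelopes[fwd, 1]
    idx <- which(diff(sign(diff(env))) == -2) + 1
    idx <- idx[env[idx] > 0.25 * max(env)]
    idx <- idx[c(TRUE, diff(idx) > 200)]
    max(vapply(seq_len(length(idx) - 1), function(j)
      min(env[idx[j]:idx[j + 1]]) / max(env), numeric(1)))
  }
  expect_lt(valley(3000), 0.01)
  expect_gt(valley(200), 0.015)
})

test_that("degenerate initial occupancies are rejected", {
  cell <- bare_cell()
  expect_error(simulate_sequential(sequential_params(0, 0, 10, 10), cell,
                                   w_dc, init = c(thX = 0.8, thZ = 0.5)),
               "simplex")
})
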