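---
title: "Models and methods: FTACV simulation and inference for surface-confined redox couples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: FTACV simulation and inference for surface-confined redox couples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftacv)
```

## The scientific problem

A redox protein adsorbed as a stable film on an electrode exchanges
electrons with the electrode without diffusion. Large-amplitude
Fourier-transformed AC voltammetry (FTACV) superimposes a sine wave
(amplitude $\Delta E$, frequency $f$) on a slow triangular dc ramp,

$$E(t) = E_{dc}(t) + \Delta E \sin(\omega t + \eta), \qquad \omega = 2\pi f,$$

and analyses the current per harmonic of $f$. The higher harmonics respond
only to fast Faradaic processes, so they separate the protein's
electron-transfer signal from the slow capacitive background that dominates
dc voltammetry of dilute protein films.

This package simulates and fits such experiments for a two-electron,
proton-coupled couple: a disulfide-type centre that is reduced either by

* two sequential one-electron transfers through a radical intermediate
  (states X, Y, Z with apparent potentials $E^0_{app,1}$, $E^0_{app,2}$), or
* one concerted two-electron transfer (X to Z directly).

Protonation steps are assumed fast and reversible, so each electron
transfer carries *apparent* parameters that absorb the pKa and pH terms of
its coupled chemistry. The pH dependence of the two apparent potentials is
then interpreted with Laviron's nine-member square scheme.

## Faradaic model

Surface populations $\theta_X + \theta_Y + \theta_Z = 1$ evolve by
Butler-Volmer kinetics evaluated at the effective (post-Ohmic-drop)
potential:

$$k_{red} = k^0 e^{-\alpha n F (E - E^0)/RT}, \qquad
  k_{ox} = k^0 e^{(1-\alpha) n F (E - E^0)/RT},$$

with $n = 1$ per step for the sequential mechanism and $n = 2$ (exponents
scaled by 2, so the equilibrium ratio obeys the two-electron Nernst
equation) for the concerted mechanism. We adopt the IUPAC sign convention:
oxidative current positive. The Faradaic current is
$I_f = F\Gamma\, d(\theta_X - \theta_Z)/dt$, with $\Gamma$ the total
electroactive amount (moles); per-area coverage is $\Gamma/S$. We store
$\Gamma$ as total moles because the area scalar $S$ (0.03 cm$^2$ in the
study preset) multiplies only the capacitive term; both per-area and total
readings of a coverage are thereby supported.

The non-Faradaic background is a dual cubic "capacitance polynomial",
$C(E) = S c_0 (1 + c_1 E + c_2 E^2 + c_3 E^3)$, with separate coefficient
sets for the forward and reverse dc sweeps, switching exactly at the ramp
reversal (no blending). A polynomial that goes negative inside the window
is physically meaningless and is clamped at zero with a warning. The
uncompensated resistance couples everything through
$E_{eff} = E_{app} - R_u I_{tot}$ with
$I_{cap} = C(E_{eff})\, dE_{eff}/dt$; the capacitor must be driven by the
effective-potential rate, otherwise $R_u$ would be invisible to the
background current and unrecoverable in the first fitting step.

## Numerical scheme

At frozen potential the occupancy ODE is *linear*, so the integrator
advances each substep exactly with the closed-form $2\times2$ matrix
exponential (the rate matrix has real negative eigenvalues). This is
unconditionally stable: rate constants of $10^5\,$s$^{-1}$ and beyond --
needed for the reversible-limit studies -- cost nothing extra. Two
numerical points deserve emphasis:

* **Current evaluation.** Near equilibrium the instantaneous rate
  expression $F\Gamma(k_{ox}\theta_Y - k_{red}\theta_X + \dots)$ is the
  difference of two terms $\sim k$ that cancel to the tiny net current;
  any occupancy error is amplified by $k$. The simulator instead reports
  the charge flux $F\Gamma\, d(\theta_X-\theta_Z)/dt$ by second-order
  finite differences, which is exact for the relaxed solution and
  well-conditioned at any $k$.
* **Ohmic drop.** With $R_u > 0$ the system is a semi-explicit DAE. Each
  substep solves the midpoint-discretized constraint for the new effective
  potential by secant iteration (tolerance $10^{-12}$ V, bisection
  fallback on the monotone residual), using the substep-average Faradaic
  current for the same conditioning reason. The reported trace columns are
  made exactly consistent: $I_{tot} = I_f + I_{cap}$ and
  $E_{eff} = E_{app} - R_u I_{tot}$ hold to machine precision.

Output lands on a uniform grid of `samples_per_period * f` points per
second (default 400 per period, at least 200 so nine-plus harmonics sit
well below Nyquist), on the half-open interval $[0, t_{end})$ -- at the
study settings this makes the sample count highly composite (fast FFTs)
and the trace exactly periodic. Default `n_sub = 4` integration substeps
per sample keep the reversible-limit error below 1% of peak current
(verified against the Nernst-equilibrium oracle and against
`deSolve::lsoda` at tolerances $10^{-8}/10^{-10}$ in the test suite); the
fitting routines use `n_sub = 2` or 1, which is ample at quasi-reversible
rates and matched between generator and fit.

We considered a generic adaptive stiff solver for the occupancy system and
rejected it: the exact exponential step is faster by orders of magnitude
in the multi-start fits and has no stability ceiling, while `deSolve`
remains in the test suite as an independent oracle.

## Harmonic decomposition

Harmonics are isolated by the classical sequence: FFT of the total
current, rectangular band selection about $n f$ (half-width default
$0.45 f$, configurable; the original study does not state its window), and
inverse FFT. The magnitude envelope of order $n \ge 1$ is twice the
modulus of the one-sided (analytic) band signal. The first and last full
ac period are excluded from residual computations, where inverse-transform
ringing concentrates. One reversible-limit signature worth noting: at the
study amplitude ($\Delta E = 150$ mV) the simulated $n$-th harmonic of a
one-electron couple resolves $n$ envelope lobes with near-zero current
between them -- the lobe count grows with order, and valley filling is the
fingerprint of finite electron-transfer kinetics used in the
model-discrimination figures.

## Two-step inverse problem

**Step 1 (time domain).** Regions with negligible Faradaic current are
selected by a potential-window rule: $|E_{dc}(t) - E_{center}| >$
`half_window` (default 0.2 V $\gtrsim \Delta E$ + wave width; the windows
retain well under 0.1% of the Faradaic charge on synthetic truths). On
those regions the measured current is entirely capacitive, so for a trial
$R_u$ the effective potential is known *exactly* from the data,
$E_{eff} = E_{app} - R_u I$, and the model is linear in the four
coefficient products of each sweep direction. Each of the `n_restarts`
(default 10) optimizations therefore profiles the eight polynomial
coefficients out by exact least squares and minimizes over $R_u$ alone
from a uniform random start. This recovers coefficients and $R_u$ to well
under 1% on noise-free backgrounds; a joint 9-parameter derivative-free
search stalls in the shallow $R_u$ valley (the resistance is only weakly
identified by the background current -- consistent with the wide scatter
of fitted $R_u$ values, 9--120 $\Omega$, in this kind of analysis, and
with the insensitivity of the recovered Faradaic parameters to $R_u$
across that range, which the test suite checks directly).

**Step 2 (frequency domain).** With background and $R_u$ frozen, the
Faradaic parameters -- $(E_1, E_2, k_1, k_2)$ or $(E_3, k_3)$, plus the
phase $\eta$ and coverage $\Gamma$ -- minimize the Euclidean distance
between the discrete Fourier transforms of simulated and measured total
current. The objective band covers harmonic orders 1--10 by default: the
aperiodic band is excluded because residual background-extrapolation error
concentrates there and would otherwise swamp the Faradaic information
(configurable via `min_order`/`max_order`). Transfer coefficients are
fixed at 0.5 unless `fit_alpha = TRUE` (then bounded in [0.4, 0.6]); rate
bounds default to $(0, 4000]$ s$^{-1}$; $\eta$ is fitted about zero in
$(-\pi/4, \pi/4)$; $\Gamma$ in [0.1, 20] pmol.

The optimizer behind the multi-start contract is bounded Nelder-Mead on
unit-scaled parameters with box projection plus a quadratic penalty:
derivative-free, bound-constrained, restarts uniform in the bounds. The
projection (rather than a smooth transform) makes a plateau that slopes
toward a bound terminate *exactly at the bound*, which is how reversible
rate constants report themselves: on data from a couple faster than the
experiment resolves, the fitted $k$ pins at the 4000 s$^{-1}$ ceiling with
its at-bound flag set, and the objective surface over $(k_1, k_2)$ is flat
above roughly 2000 s$^{-1}$ -- the experiment only bounds the rates from
below.

Each restart runs Nelder-Mead up to twice, re-launching from the first
endpoint with a fresh simplex -- the standard remedy for premature
simplex collapse in six dimensions.

Model discrimination runs the step-2 fit under both mechanisms and
compares objectives (no evidence-based selection; the study compares
objective values only). The concerted model is fitted first and, since
the sequential model nests it at $E_1 = E_2 = E_3$, its solution seeds
one additional start of the sequential fit (cascade initialization);
uniform random restarts are retained alongside. Two reversible mechanisms converge when the
crossed separation $E_2 - E_1$ reaches +200 mV: the residual intermediate
population is then $\theta_Y \le 1/99$, leaving an irreducible ~1% peak
difference pointwise but only ~0.4% in RMS terms -- visually
indistinguishable traces. We therefore quantify "converged" by RMS
deviation relative to peak amplitude, and "distinguishable" by the same
metric an order of magnitude larger at +25 mV separation.

## Square scheme and Pourbaix inference

The pH dependence of the two apparent potentials follows the nine-member
square scheme: each redox level (oxidized, intermediate, reduced) carries
up to two protonations with acid constants $K_{aA}..K_{aF}$, and

$$E^0_{app,1} = E^0_1 - \frac{RT}{F}\ln
  \frac{1 + [H^+]/K_{aB} + [H^+]^2/(K_{aA}K_{aB})}
       {1 + [H^+]/K_{aD} + [H^+]^2/(K_{aC}K_{aD})},$$

$$E^0_{app,2} = E^0_2 - \frac{RT}{F}\ln
  \frac{1 + [H^+]/K_{aD} + [H^+]^2/(K_{aC}K_{aD})}
       {1 + [H^+]/K_{aF} + [H^+]^2/(K_{aE}K_{aF})},$$

with $E^0_1, E^0_2$ the alkaline-limit potentials. The brackets are
evaluated in the log domain (log-sum-exp), so extreme trial pKas cannot
overflow. Model slopes approach 0, $-59.2$ or $-118.4$ mV/pH in pure
regimes at 298.15 K.

The fit maximizes a joint Gaussian likelihood of all (Eapp1, Eapp2)
records -- each repeated experiment enters as an independent observation,
not a per-pH mean -- with independent noise scales on the two potentials.
The noise scales are profiled out analytically (their conditional MLEs are
the residual RMS values), leaving a bounded 8-parameter search with 20
uniform restarts (pKa bounds $[-2, 16]$, T fixed at 298.15 K). Only pKas
inside the observed pH range are constrained; a *profile likelihood* per
parameter (all other parameters re-optimized on a grid across the bounds,
warm-started continuation outward from the MLE) flags the rest as
unidentified when the region within 2 log-likelihood units of the profile
maximum spans more than a quarter of the bound range. A conditional slice
is not enough here: an out-of-range pKa and its alkaline-limit potential
trade off along a ridge, so each looks sharp conditionally while being
jointly unconstrained. On the packaged study table the diagnostic leaves
exactly the two crossed-in-range pKas and the first alkaline-limit
potential identified.

On the bracket structure: the $[H^+]$ term of a level's bracket carries
the dissociation constant of its *singly* protonated species, the
$[H^+]^2$ term adds the doubly protonated one. So the pKa governing
deprotonation of the fully protonated, fully reduced state is $pK_{aE}$,
and that of the singly protonated one-electron intermediate is $pK_{aD}$.
We report all six and state this functional assignment rather than
guessing any shorthand numbering.

Posterior uncertainty comes from Haario-style adaptive Metropolis: flat
priors inside the bounds (noise scales flat in log), proposal covariance
$2.4^2/d$ times the running sample covariance (regularized, adapted every
50 iterations after 200), 50% burn-in, split-chain potential-scale
reduction with a 1.05 warning threshold. Chains are seeded per index, so a
run is bit-reproducible and extending `n_iter` preserves the earlier
draws. On well-identified synthetic data the posterior means agree with
the MLE within one posterior standard deviation; on the packaged study
table the acid-side pKas ($pK_{aA,B,C}$) return prior-wide posteriors
spanning several pH units, exactly the behaviour expected when no
observation crosses those constants.

## Synthetic data: what it emulates and what it does not

The generator reproduces the study conditions: $f = 8.96$ Hz,
$\Delta E = 150$ mV, dc scan rate 22.4 mV s$^{-1}$, 0.03 cm$^2$ electrode,
coverage ~3.5 pmol, temperature 298.15 K, a dual cubic background of
pyrolytic-graphite magnitude ($c_0 \approx 100{-}120\ \mu$F cm$^{-2}$ with
mild potential dependence -- values chosen once as realistic, since the
study reports only their magnitude class) and $R_u = 27\ \Omega$ (the
impedance-derived estimate; fitted values scatter across 9--120 $\Omega$).
The default dc window 0.05 to $-0.45$ V spans the apparent potentials
observed between pH 4 and 9. Noise is additive i.i.d. Gaussian on the
total current; the default level targets a fundamental-harmonic SNR of
100, at which nine or more harmonics stay resolvable -- matching the
qualitative claim for the measured data. Eapp-versus-pH tables add
Gaussian noise per record in the Table-1 layout (three experiments at each
of pH 4--9).

Real instrument features *not* emulated: mains hum, drift, electrode film
loss, non-Gaussian noise, and molecule-to-molecule kinetic or
thermodynamic dispersion (the study concludes dispersion is negligible for
this system, and dispersion modelling is out of scope here). Passing
synthetic-recovery tests therefore demonstrates correctness of the
estimation machinery under the stated noise model, not robustness to every
artifact of measured traces.

Test and verification problem sizes are the package's own choices: the
closed-form and oracle checks run on 0.3--0.4 V windows at 400 samples per
period; the multi-start recovery and 20-replicate discrimination studies
use a window just covering the wave, 200 samples per period, and (for the
replicate study) a 4x faster ramp, keeping each replicate's two fits to a
few seconds while leaving the discrimination margin at an order of
magnitude in objective.

## Known limitations

* Butler-Volmer kinetics only (no Marcus-Hush-Chidsey); adsorbed species
  only (no diffusion); a single area scalar for electrode geometry.
* The two-step procedure inherits any background misspecification into the
  Faradaic stage; the order-1..10 objective band mitigates but does not
  remove this.
* The square-scheme fit treats temperature as fixed and pKas as
  pH-independent constants; proton-transfer kinetics (accessible only to
  high-frequency data) are not modelled.
* With crossed potentials separated by $\gtrsim 200$ mV the sequential and
  concerted mechanisms are empirically indistinguishable at realistic
  noise -- a property of the physics, not a failure of the fit.

## A worked pipeline

```{r pipeline, eval = FALSE}
w <- study_waveform(E_start = -0.05, E_reverse = -0.38,
                    samples_per_period = 200)
truth <- ftacv_truth("sequential",
                     sequential_params(-0.215, -0.206, 4000, 4000),
                     cell = study_cell(), waveform = w, snr = 100, seed = 1)
gen <- generate_ftacv(truth, n_sub = 2)

cap <- fit_capacitance(gen$trace, seed = 1)
cmp <- compare_models(gen$trace, cap, n_restarts = 10, seed = 2)
print(cmp)

fit <- fit_square_scheme(hypd_table1("pourbaix"), n_restarts = 20, seed = 3)
summary(fit)
post <- sample_posterior(hypd_table1("pourbaix"), fit, seed = 4)
print(post)
```
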