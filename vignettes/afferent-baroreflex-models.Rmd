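---
title: "Afferent baroreceptor models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Afferent baroreceptor models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Baroreceptors (BRs) are stretch-sensitive afferent neurons in the aortic
arch and carotid sinus whose firing rate encodes arterial pressure. Their
response to pressure stimuli shows a reproducible repertoire: a firing
threshold, saturation near 120–140 Hz, overshoot followed by
multi-timescale adaptation after a pressure step, post-excitatory
depression (PED) after a pressure drop, hysteresis between rising and
falling pressure, and rectification (silencing in the troughs) under
large-amplitude periodic forcing. `baroafferent` implements a modular
family of models for this transduction chain together with the estimation
machinery needed to fit them to firing-rate recordings, and synthetic-data
generators that stand in for the classical rat protocols.

# The model family

The transduction is split into three stages, each a small exchangeable
component. Differential equations enter only through the middle
(mechanoreceptor) stage and, optionally, a viscoelastic wall; every ODE in
the family is linear and time-invariant, which the numerics exploit.

## Arterial wall deformation

Pressure $p$ (mmHg) maps to circumferential wall strain $\varepsilon_w$
(dimensionless, zero at zero transmural pressure — the convention that
makes the published compliance magnitude $k_{wall} = 0.0063$/mmHg
consistent, e.g. $\varepsilon_w(127) = 0.8001$).

* **Linear elastic.** A thin-walled isotropic tube under Laplace's law:
  $\varepsilon_w = k_{wall}\,p$, with $k_{wall} = r_0 / (E h)$ folding
  Young's modulus, wall thickness and unstressed radius into one
  compliance. Adequate over narrow pressure ranges.
* **Nonlinear elastic.** The pressure–area relation of large arteries is
  sigmoidal: $A(p) = A_0 + (A_m - A_0)\,p^k / (\alpha^k + p^k)$, with
  $A_0 = 1$, $A_m = 32.6$ mm², half-saturation pressure $\alpha = 150$
  mmHg, steepness $k = 10$. Strain follows from the radius ratio,
  $\varepsilon_w = \sqrt{A/A_0} - 1$. This is the component that lets one
  parameter set fit responses across different baseline pressures.
* **Standard linear solid (SLS).** A Maxwell element in parallel with a
  spring, written in pressure–strain form as
  $\tau_a \dot\varepsilon_w + \varepsilon_w = k_{wall}(p + \tau_b \dot p)$
  with creep time $\tau_a = 0.028$ s and stress-relaxation time
  $\tau_b = 0.01$ s; the instantaneous response is the fraction
  $\tau_b/\tau_a$ of the static one. The pressure derivative is always
  supplied analytically by the stimulus object — sampled trajectories are
  never differentiated numerically.

All three are instances of quasi-linear viscoelasticity (QLV),
$$\varepsilon_w(t) = \int_{-\infty}^{t} K(t-s)\,
  \frac{d\varepsilon_e(p(s))}{ds}\,ds,$$
with creep kernel $K \equiv 1$ and the respective elastic response for the
elastic walls, and $K(t) = 1 - (1 - \tau_b/\tau_a)e^{-t/\tau_a}$,
$\varepsilon_e = k_{wall} p$ for the SLS. Pre-record history is assumed
relaxed at the initial pressure, contributing
$K(\infty)\varepsilon_e(p(t_0))$. The test suite verifies each reduction
numerically (`qlv_from_wall()`), by exact recursive filtering for
exponential-sum kernels and by direct trapezoidal convolution as the
independent quadrature.

## Mechanoreceptor coupling

The nerve endings couple viscoelastically to the wall: $n \in \{1,2,3\}$
Voigt bodies (spring $K_i$ ∥ dashpot $B_i$) in series with a sensing
spring $K$. With rate parameters $\alpha_i = K/B_i$ and
$\beta_i = (K+K_i)/B_i$ (1/s) — the spring/dashpot constants themselves
are structurally non-identifiable — the per-body strains obey
$$\dot\delta_i = \alpha_i(\varepsilon_w - \varepsilon_1)
  - (\beta_i - \alpha_i)\,\delta_i ,$$
and the package integrates the cumulative strains
$\varepsilon_j = \sum_{i \ge j} \delta_i$, chosen so that the sensed
strain is always the strain across the sensing spring,
$\varepsilon_{ne} = \varepsilon_w - \varepsilon_1$, for every $n$. The
characteristic polynomial has closed-form coefficients; for $n = 2$,
$\lambda^2 + (\beta_1+\beta_2)\lambda + (\beta_1\beta_2 -
\alpha_1\alpha_2)$, and `relaxation_timescales()` evaluates the roots by
the quadratic/trigonometric-cubic formulas, independently of the numeric
eigendecomposition the tests compare against. Repeated $\beta_i$ collapse
two timescales and are warned about at construction.

Two structural facts drive everything downstream:

* the **DC gain** of $\varepsilon_{ne}$ is
  $\prod_i(\beta_i - \alpha_i) / c_0$ (with $c_0$ the constant polynomial
  coefficient): strictly inside $(0,1)$ when all $\beta_i > \alpha_i$
  (partial adaptation), and exactly zero when any $\beta_i = \alpha_i$
  (that Voigt body has a zero spring — a pure dashpot — and static strain
  is eventually fully absorbed: complete adaptation);
* the step response superposes $n$ exponential modes, which is what makes
  adaptation multi-timescale.

The classical nominal values $\alpha = (0.5, 0.4, 1)$,
$\beta = (0.5, 2, 10)$ 1/s sit exactly on the complete-adaptation boundary
($\beta_1 = \alpha_1$). A model on that boundary cannot show a firing
threshold on a slow ramp or a pressure-dependent steady discharge, so the
package's *preferred* configuration instead adopts a published estimated
pair with partial adaptation; see *Choice of the preferred configuration*.

## Firing-rate generation

* **Linear amplifier**: $f = s_1 \varepsilon_{ne} + s_2$ (nominal gain 480
  Hz/strain, shift 100 Hz). Deliberately *not* clamped at zero by default:
  its negative excursions under rectifying stimuli are the documented
  failure mode that motivates a threshold neuron (a clamp flag exists for
  downstream use).
* **Leaky integrate-and-fire**: the mechanoreceptor current
  $I = s_1\varepsilon_{ne} + s_2$ (nA) charges an RC membrane
  ($C_m$ nF, leak $g$ µS, voltage relative to the equilibrium potential).
  The threshold-charging time under constant current is
  $T_{th} = (C_m/g)\ln\!\big(I/(I - gV_{th})\big)$ for $I > gV_{th}$ and
  infinite otherwise, and the instantaneous rate is
  $f = 1/(T_{th} + \Delta)$, zero below threshold. The refractory period
  $\Delta = 7$ ms is fixed by the observed ~140 Hz ceiling. Note
  $f \to 0$ *continuously* (though logarithmically slowly) as
  $I \downarrow gV_{th}$; the map is piecewise-defined and non-smooth,
  which is why gradient-based fitting is refused for it, but it has no
  jump discontinuity.

Firing is an algebraic output of the instantaneous strain — the ODE states
never depend on $f$, so the piecewise branch never enters the integrator.
The rate interpretation (rather than spike-level simulation) is exact for
constant current and verified against an event-based reset simulation in
the tests.

# Composite models and initialization

Six canonical composites are named `<wall>-<chain>-<neuron>`: `le-v1-l`,
`le-v2-l`, `le-v3-l`, `v-v2-l`, `ne-v2-l`, `ne-v2-if`. Other combinations
simulate but are flagged non-canonical. Simulations start from the relaxed
state obtained by solving the zero-derivative system at the initial
pressure $p_0$ and derivative $\dot p_0$: elastic walls give
$\varepsilon_w(0) = \varepsilon_e(p_0)$ (no $\dot p_0$ dependence), the SLS
wall gives $\varepsilon_w(0) = k_{wall}(p_0 + \tau_b\dot p_0)$, and the
chain solves $A x = -b\,\varepsilon_w(0)$.

# Choice of the preferred configuration

The preferred model is the nonlinear wall + two Voigt bodies +
integrate-and-fire composite. The wall uses the published sigmoid values
($A_0 = 1$, $A_m = 32.6$, $\alpha = 150$, $k = 10$). The membrane constants
and the current map are **package choices** (the source literature does not
print them): $C_m = 10$ nF, $g = 1$ µS ($\tau_m = 10$ ms, nodose-neuron
scale), $V_{th} = 10$ mV, $\Delta = 7$ ms, $s_1 = 25$ nA/strain,
$s_2 = 7$ nA. They were fixed once by a static operating-point analysis.
Writing $G$ for the chain DC gain, $\nu(p) = G\,\varepsilon_w(p)$ for the
static nerve strain and $m = (gV_{th} - s_2)/s_1$ for the threshold strain
margin, the phenomenon battery requires simultaneously:

* *no rectification at the experimental 5 mmHg sinusoid amplitude*:
  $\nu(127) - m$ must exceed the AC strain amplitude
  $|H(i\omega)|\,\varepsilon_w'(127)\cdot 5 \approx 0.33$;
* *rectification at 2.5× amplitude*: the same margin must be below
  $\approx 0.83$;
* *PED at the square protocol*: the post-drop strain
  $\nu(180) + \text{(unadapted remainder)} - [\varepsilon_w(180) -
  \varepsilon_w(140)]$ must fall below $m$;
* *positive steady discharge at all protocol baselines*:
  $m < \nu(115)$;
* *a finite ramp threshold*: $m > 0$.

These inequalities bound $G$ to roughly $(0.23, 0.54)$ — ruling out both
the complete-adaptation nominal chain ($G = 0$) and strongly static chains
— and among the published estimated two-Voigt rate pairs the step-protocol
values $\alpha = (0.188, 0.4)$, $\beta = (0.304, 2)$ satisfy them with the
widest margins ($G = 0.348$, relaxation times 3.8 s and 0.49 s, well
separated for two-exponential adaptation). With $m = 0.12$ the resulting
operating points are physiological: threshold ≈ 95 mmHg on a 10 mmHg/s
ramp, baseline discharge 49–87 Hz over 115–140 mmHg, saturation ≈ 109 Hz.
An earlier draft of this analysis compared the PED undershoot against the
wrong baseline and selected constants without a PED margin; the corrected
constraint system above is the one the defaults now satisfy.

# Numerics

* **Exact modal integration.** Every composite reduces to
  $\dot x = A x + d\,g(t)$ with $A$ constant and $g$ analytic (wall strain
  of the pressure, or $p + \tau_b\dot p$). `lti_solve()` diagonalizes $A$
  and propagates each mode exactly, integrating the input term with
  quadratic interpolation through step endpoints and midpoints
  (φ-function weights, series-stabilized below $|\lambda h| = 10^{-2}$).
  On uniform grids the per-mode recurrence runs through a compiled
  recursive filter. The method is unconditionally stable — stiffness from
  spread $\beta_i$ or the fast SLS wall ($\tau_a = 28$ ms) costs nothing —
  and the only discretization error is input interpolation, $O(h^4)$
  locally: halving the default 5 ms output step changes firing traces by
  less than $10^{-6}$ relative.
* **Fallbacks and oracle.** Complex or near-defective eigenstructure falls
  back to an adaptive Dormand–Prince 5(4) integrator (`ode_rk45()`,
  tolerances $10^{-8}$) that lands exactly on requested output times; the
  same integrator is the independent cross-check for the modal path in the
  tests, with a series-based matrix exponential as a second oracle.
* **Degenerate inputs.** Zero-amplitude stimuli, equal step levels and
  empty plateaus are valid and produce constant traces; non-monotone time
  grids are rejected; chain regimes with non-negative relaxation rates
  (e.g. $\alpha_i$ too large) raise an explicit invalid-regime error from
  the closed-form root solver.

# Estimation methodology

Residuals are normalized by the record's mean firing rate,
$r_j = (f_{model}(t_j) - f_{obs,j})/\bar f$; the minimized cost is
$\sum_j r_j^2$, while fit quality is reported as RMSE in Hz,
$\sqrt{\mathrm{mean}(f_{model}-f_{obs})^2}$, and the coefficient of
determination $R^2$. Parameters are estimated on the log scale
$\theta = \theta_0 e^x$, which enforces positivity and conditions the
problem. Sensitivities are central finite differences in $x$ with relative
step $h = 10^{-4}$ — the square root of the integration tolerance, so
truncation and solver error balance. Subset selection proceeds in three
stages: two-norm ranking (insensitive parameters fixed), QR with column
pivoting on the leading right singular vectors (numerical rank at relative
tolerance $10^{-8}$; rank deficiency reduces the subset rather than
failing), then correlation pruning from
$C = \sigma^2 (S^\top S)^{-1}$: while any $|c_{ij}| > \gamma$ the less
sensitive member of the worst pair is fixed. The threshold $\gamma = 0.9$
is a configurable package default (correlations are invariant to
$\sigma^2$). Smooth composites are fitted by a Levenberg–Marquardt
iteration (Marquardt-scaled damping, forward-difference Jacobian);
integrate-and-fire composites use Nelder–Mead with one restart from the
converged simplex, because the piecewise output map invalidates gradient
methods — requesting LM for them is an error, not a silent fallback.
Simultaneous fits pool residual vectors (each normalized by its own record
mean) across stimulus/dataset pairs and estimate one shared model
parameter vector.

# Synthetic data: what it does and does not emulate

`bundled_protocols()` encodes the three classical stimulus classes — a
5 s sinusoid (127 ± 5 mmHg, sampled at 200 Hz), four 15 s smooth steps
from 115 mmHg to 128/134/137/143 mmHg (50 Hz), and a 20 s square pulse
140→180→140 mmHg with a 4.1 s plateau (50 Hz) — simulated from a chosen
composite and corrupted with additive Gaussian noise whose SD is a
fraction (default 2%) of the record's mean rate, matching the residual
normalization; multiplicative noise is available. The step onset (2 s into
the record) and the step record length are package conventions, chosen so
records cover ≈5 slow chain time constants.

The generator reproduces the *envelope* statistics of binned firing-rate
recordings, not their microstructure: no spike-count (quasi-Poisson)
variability, no inter-spike-interval binning artifacts, no slow
electrode/preparation drift, no inter-animal parameter spread, and the
generating model is by construction within the fitted family. A green
recovery test therefore establishes identifiability and optimizer
correctness under the stated noise model — not that the model family is
adequate for any particular laboratory recording.

# Feature detectors

Detectors are deterministic functions of an existing simulation and never
re-simulate. Definitions (all package conventions; the literature states
the phenomena, not numeric criteria): *silence* is $|f| \le 10^{-9}$ Hz —
exact zeros come from the sub-threshold branch, and a linear neuron's
negative rates count as (unphysical) firing, not cessation; *threshold* is
the pressure after the last silent sample of a monotone ramp, provided
firing is sustained to the ramp's end; *saturation* requires the terminal
|df/dp| to drop below 5% of its peak; *PED* is the longest contiguous
silent run after the square down-step; *hysteresis* is the signed shoelace
area of the (p, f) loop over one full triangle cycle; the *adaptation
count* is the smallest k ∈ {1,2,3} whose separable k-exponential fit of
the post-overshoot decay reaches an RMS residual below 0.5% of the decay
signal's RMS; *rectification* requires every post-transient cycle to
contain both a silent sub-interval and positive firing.

# Known limitations

* The family is rate-based; spike-train statistics (ISI distributions,
  refractory jitter) are out of scope.
* Efferent baroreflex signalling and closed-loop regulation are not
  modelled; the package provides the afferent arm only.
* Wall mechanics are isotropic thin-shell models; anisotropic multi-layer
  or large-deformation descriptions are intentionally excluded.
* Chains with more than three Voigt bodies are not supported (two
  timescales suffice for the documented phenomena).
* Uncertainty quantification beyond the sensitivity/correlation report
  (profile likelihoods, bootstrap, Bayesian posteriors) is not provided.
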