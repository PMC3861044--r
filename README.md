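# baroafferent

Mechanistic modelling of **afferent baroreceptor (BR) firing**: the neural
arm that encodes arterial blood pressure into a spike rate, the input signal
of the baroreflex. The package is aimed at cardiovascular and neural
modellers who need a compact, identifiable BR model to embed in closed-loop
circulation models, and at methodologists studying parameter estimation for
small mechanistic ODE models.

## The model family

Pressure is transduced in three physiological stages, each with exchangeable
component models:

1. **Arterial wall deformation** — pressure p (mmHg) to circumferential wall
   strain ε_w:
   - linear elastic (Laplace's law): ε_w = k_wall·p
   - nonlinear elastic: sigmoidal pressure–area relation
     A(p) = A₀ + (A_m − A₀)·pᵏ/(αᵏ + pᵏ), with ε_w = √(A/A₀) − 1
     (saturates at low and high pressure)
   - standard linear solid (viscoelastic):
     τ_a ε̇_w + ε_w = k_wall (p + τ_b ṗ)

   All three are instances of the quasi-linear viscoelastic convolution
   ε_w(t) = ∫ K(t−s) dε_e(p(s)) — a unification the test suite verifies
   numerically.

2. **Mechanoreceptor coupling** — wall strain to nerve-ending strain ε_ne
   through n = 1–3 Voigt bodies in series with a spring:
   ε_ne = ε_w − ε₁, with linear relaxation dynamics in rate constants
   αᵢ = K/Bᵢ, βᵢ = (K+Kᵢ)/Bᵢ. The chain produces overshoot and
   multi-exponential adaptation; its relaxation times are the roots of a
   closed-form characteristic polynomial (e.g. λ² + (β₁+β₂)λ + β₁β₂ − α₁α₂
   for n = 2).

3. **Firing-rate generation** — ε_ne to rate f (Hz):
   - linear amplifier f = s₁ ε_ne + s₂, or
   - leaky integrate-and-fire: stimulus current I = s₁ ε_ne + s₂ charges an
     RC membrane; f = 1/(T_th + Δ) with T_th = (C_m/g)·ln(I/(I − gV_th)) for
     I > gV_th and f = 0 below threshold.

Six canonical composites (`le-v1-l` … `ne-v2-if`) are supported; the
**preferred model** (nonlinear wall + 2 Voigt bodies + integrate-and-fire)
reproduces the full battery of classical BR phenomena: threshold,
saturation, overshoot with two-timescale adaptation, post-excitatory
depression (PED), hysteresis, and rectification.

The estimation toolkit implements the accompanying methodology: residuals
normalized by mean firing, finite-difference sensitivities on log-scaled
parameters, two-norm sensitivity ranking, QR–SVD subset selection with
correlation pruning, and Levenberg–Marquardt (smooth models) or Nelder–Mead
(integrate-and-fire models) fitting, including simultaneous fits of several
stimulus/response records.

## Worked example

```r
library(baroafferent)
model <- preferred_model()

# square pressure pulse 140 -> 180 -> 140 mmHg: adaptation + PED
sim <- simulate_br(model, stimulus_square(140, 180, 4.6, 8.7),
                   seq(0, 20, by = 0.005))
sim
#> <BR simulation: ne-v2-if, 4001 points, t in [0, 20] s, f in [0, 118] Hz>
feature_report(list(square = sim))
#> <BR qualitative feature report>
#>   ped_silence              0.305

# fit a synthetic step-protocol record (115 -> 143 mmHg, 2% noise)
spec <- bundled_protocols(noise_sd_fraction = 0.02, seed = 1)$step4
ds   <- generate_dataset(spec)
fit  <- fit_br(model, spec$stimulus, ds, c("s1", "s2", "alpha1", "beta1"))
fit
#> <BR fit: ne-v2-if, nm, converged>
#>      s1      s2  alpha1   beta1
#> 25.0800  6.9250  0.1925  0.3133
#>   RMSE = 1.881 Hz, R^2 = 0.9754, iterations = 366
```

Reading the output: the square pulse drives firing from its ~87 Hz baseline
to a ~118 Hz overshoot that adapts during the plateau; after the down-step
the neuron falls silent for 0.305 s (post-excitatory depression) before
recovering — the behaviour that motivates the integrate-and-fire component,
since a linear neuron would instead swing negative. The Nelder–Mead fit
recovers the generating current gain/shift (25, 7) and the first Voigt pair
(0.188, 0.304) from noisy data to within a few percent, with a residual
RMSE of 1.9 Hz against a 92 Hz mean rate.

## Command line

A CLI covering simulation, synthetic data, fitting, sensitivity ranking and
feature detection ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/baroafferent-cli.R", package = "baroafferent"))')
Rscript $CLI simulate --model model.json --stimulus stim.json \
        --t0 0 --t1 20 --dt 0.005 --out trace.csv
Rscript $CLI make-data --protocol square --noise 0.02 --seed 42 --out data.csv
```

## Documentation

The methods vignette (`vignettes/afferent-baroreflex-models.Rmd`) describes
the model family, its assumptions, the parameter choices and their units,
what the synthetic-data generator does and does not emulate, and the
package's numerical decisions.
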