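# diffenc

Design and analysis of motion-compensated diffusion encoding gradient
waveforms for spin-echo diffusion MRI.

## The problem

Liver diffusion-weighted imaging loses signal near the heart because bulk
motion through the diffusion gradients dephases spins. The phase of a spin
with position x₀, velocity v and acceleration a is set by the gradient
moments of the effective waveform G_eff (physical gradient, polarity
flipped before the 180° pulse):

    Mₙ = γ ∫ G_eff(t) tⁿ dt,     φ = M₀x₀ + M₁v + ½ M₂a,

with γ = 2.678×10⁸ rad/s/T. Velocity compensation (M₁ = 0) and
acceleration compensation (M₁ = M₂ = 0) remove the dropout but also keep
flowing blood bright, which can mimic lesions. `diffenc` builds symmetric,
concomitant-field-balanced trapezoid waveforms whose residual M₁/M₂
weighting is tuned continuously by a single timing-shift parameter t_S —
each side of the 180° pulse carries a short (a) and a long (b) pulse of
opposite polarity, and shifting durations to a + t_S and b − t_S moves both
residual fractions |M₁|/M₁max = |M₂|/M₂max at ≈ 0.35 per ms, at constant
echo time and b-value. The package computes all moments and b-values of
piecewise-linear waveforms in closed form, provides rectangular-pulse
closed-form oracles, and includes a small ballistic-flow (IVIM-type) liver
signal model with two-point ADC estimation.

## Worked example

```r
library(diffenc)

acc <- build_acceleration_compensated(side = 23, pause = 10, ramp = 1.3,
                                      target_b = 800)
acc$timings
#> <accel_timings> a = 8.2630 ms, b = 14.7370 ms, c = 10.00 ms, ramp = 1.30 ms,
#>                 t_S = 0.000 ms, b-value 800 s/mm^2

format_report(cmd_report(default_run_config()))
#>                      scheme   b      M1      M2 frac_M1 frac_M2  balance
#> 1                 monopolar  50    1.45 8.1e-02   1.000   1.000 0.00e+00
#> 2                 monopolar 800    5.82 3.3e-01   1.000   1.000 0.00e+00
#> 3      velocity-compensated  50 5.3e-14 4.2e-02   0.000   0.519 0.00e+00
#> 4      velocity-compensated 800 2.1e-13 1.7e-01   0.000   0.519 0.00e+00
#> 5  acceleration-compensated  50   5e-14 4.7e-15   0.000   0.000 0.00e+00
#> 6  acceleration-compensated 800   2e-13 1.9e-14   0.000   0.000 0.00e+00
#> 7           84%-compensated  50    0.23 1.3e-02   0.159   0.159 0.00e+00
#> 8           84%-compensated 800    0.93 5.2e-02   0.159   0.159 0.00e+00
#> 9           67%-compensated  50    0.49 2.7e-02   0.337   0.337 0.00e+00
#> 10          67%-compensated 800    1.96 1.1e-01   0.337   0.337 0.00e+00
```

Reading the table: `M1` (s/mm) and `M2` (s²/mm) are the absolute first and
second gradient moments at each b-value (s/mm²); the monopolar row defines
the references M₁max/M₂max, so its fractions are 1. The
velocity-compensated scheme nulls M₁ at any pause length and keeps 52 % of
the monopolar M₂; the solved acceleration-compensated scheme
(a ≈ 8.26 ms) nulls both. Shifts of t_S = 0.45 and 0.95 ms give residual
fractions ≈ 0.16 and ≈ 0.34, i.e. 84 %- and 67 %-compensated encodings.
`balance` is the first-order concomitant-field imbalance ∫G²dt(pre) −
∫G²dt(post), zero for every scheme by symmetry.

A command-line interface wraps the same functions:

```sh
exec/diffenc build --out-dir waveforms     # sampled CSV + breakpoint JSON
exec/diffenc report --check                # moment table + rect oracles
exec/diffenc sweep --t-max 1.5             # fraction vs t_S, fitted slope
exec/diffenc simulate                      # liver model signals and ADCs
exec/diffenc check waveforms/monopolar_b800.csv
```

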