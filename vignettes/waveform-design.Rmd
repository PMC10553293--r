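---
title: "Designing motion-compensated diffusion encodings with diffenc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing motion-compensated diffusion encodings with diffenc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffenc)
```

## The problem

Diffusion-weighted imaging of the liver suffers from cardiac-driven bulk
motion: spins moving through the strong diffusion gradients accumulate
motion-dependent phase, which dephases voxels near the heart (left liver
lobe) and produces signal dropout. The phase accrued by a spin at position
$x_0$ moving with constant velocity $v$ and acceleration $a$ is governed by
the gradient moments of the *effective* waveform $G_{\mathrm{eff}}$ (the
physical gradient with its polarity negated before the refocusing pulse):

$$M_n = \gamma \int_0^{T} G_{\mathrm{eff}}(t)\, t^n\, dt, \qquad
\phi = M_0 x_0 + M_1 v + \tfrac12 M_2 a,$$

with $\gamma = 2.678\times 10^{8}$ rad/s/T. A velocity-compensated encoding
has $M_1 = 0$; an acceleration-compensated one has $M_1 = M_2 = 0$. Full
compensation, however, also preserves the signal of flowing blood, so
vessels turn bright and can mimic lesions. `diffenc` implements a family of
symmetric, analytically described waveforms whose residual $M_1$ and $M_2$
weighting is tuned *continuously* by a single timing-shift parameter,
letting the user trade dropout correction against black-blood contrast at a
constant echo time.

## Waveform representation and the moment engine

Schemes are ordered sets of trapezoidal pulses around an instantaneous
180° pulse. The effective waveform is exactly piecewise linear, so all
moments and the b-value
($b = \int q^2 dt$, $q(t) = \gamma\int_0^t G_{\mathrm{eff}}$)
are integrals of polynomials and are evaluated in closed form segment by
segment — no quadrature, no sampling. An adaptive-quadrature oracle is used
in the test suite to confirm agreement to better than $10^{-8}$ relative on
randomized schemes.

Two conventions matter and are deliberate:

* **Time origin at the start of the encoding.** The published absolute
  $M_2$ values are reproduced only with $t = 0$ at the first gradient
  point (the rectangular-limit hand calculation gives
  $|M_2| \approx 0.328$ s²/mm against the printed 0.33); an
  excitation-referenced origin would change $M_2$ by $2\,\Delta t\, M_1$.
  The convention is recorded in every `effective_waveform`.
* **The 180° pulse is instantaneous and centred in the pause.** Its exact
  position inside the 10 ms pause is not otherwise constrained; the
  symmetric choice preserves the concomitant-balance argument and does not
  affect the moments (no gradient is played there).

Amplitudes enter all moments linearly and the b-value quadratically, so
scaling a scheme to a target b-value is exact:
$G \mapsto G\sqrt{b_{\mathrm{target}}/b}$. All pulses within a scheme share
one absolute amplitude; only the polarity pattern differs.

## The five reference encodings

The reference geometry is 23 ms of gradient before the 180° pulse, a 10 ms
pause, and 23 ms after (56 ms total), with 1.3 ms ramps:

* **Monopolar** — one trapezoid per side, same polarity. Maximal moments
  per unit b; defines the references $M_1^{\max}, M_2^{\max}$.
* **Velocity-compensated** — built by the concatenation rule
  $G_p, -G_p, [\text{pause}], -G_p, G_p$ applied to an 11.5 ms trapezoid;
  $M_1 = 0$ for *any* pause length.
* **Acceleration-compensated** — per side a short pulse (duration $a$,
  outermost) and a long pulse ($b = 23 - a$) of opposite polarity. $a$ is
  found by bisection (`stats::uniroot`, tolerance $10^{-9}$ ms) so that
  $M_1 = 0$ on the exact trapezoid waveform; $M_2 = 0$ then follows from
  the odd symmetry of the effective waveform about the encoding midpoint
  ($M_2 = T \cdot M_1$ for any odd-symmetric waveform with $M_0 = 0$).
* **Partially compensated** — starting from the solved timings, the shift
  $t_S$ lengthens the short pulses to $a + t_S$ and shortens the long ones
  to $b - t_S$. The pause, total duration and echo time are untouched; the
  amplitude is re-solved for the target b after every shift, because the
  published moment values are defined at fixed b.

```{r five}
acc <- build_acceleration_compensated(side = 23, pause = 10, ramp = 1.3,
                                      target_b = 800)
acc$timings
moments(build_monopolar(target_b = 800))
moments(apply_timing_shift(acc$timings, 0.45))
```

Because every scheme deposits the same $\int G^2 dt$ on both sides of the
refocusing pulse, the first-order concomitant (Maxwell) phase is balanced
by construction; `concomitant_balance()` verifies this and returns the
signed imbalance for arbitrary schemes.

## The single-parameter tuning law

For idealized rectangular pulses the first moment of the short/long family
is proportional to $(a+b+c)(b-a) - 2ab$ and the second moment to
$(2a+2b+c)\left[(a+b+c)(b-a) - 2ab\right]$ — the package asserts this
factorization symbolically on random triples. Differentiating at the
compensated point gives

$$\frac{dM_1}{dt_S} = -2\gamma G\,(2b + c), \qquad
\frac{dM_2}{dt_S} = (2a + 2b + c)\frac{dM_1}{dt_S},$$

so both residual fractions $|M_1|/M_1^{\max}$ and $|M_2|/M_2^{\max}$ grow
at the *same* relative rate — in this geometry the two fractions coincide
to $\sim 10^{-13}$, because the family and its monopolar reference are both
odd-symmetric, making $M_2/M_1$ equal to the encoding duration for each.
On the trapezoid scheme the finite-difference slope at $t_S = 0$ is
$\approx 0.347$ per ms (rectangular limit: $\approx 0.325$ per ms); shifts
of 0.45 and 0.95 ms therefore give residual fractions of about 0.16 and
0.34, i.e. 84%- and 67%-compensated encodings. Note the common shorthand:
the *compensation level* is $1 -$ the residual fraction, so "84%
compensated" means fractions of 0.16 — the alternative reading, that the
fractions themselves equal 0.84/0.67, is inconsistent with the absolute
moment values and is not used here.

The tuning map is mildly curved: over $t_S \le 1.5$ ms the fraction
deviates from a straight line through the origin by up to $\approx 2\%$ of
its value (the linear coefficient itself predicts 0.157 where the exact
fraction at $t_S = 0.45$ ms is 0.160). `solve_shift_for_fraction()`
therefore inverts the exact map by bisection rather than dividing by the
slope. The slope is independent of the b-value since the fractions are
amplitude-normalized.

Degenerate inputs are rejected early: pulses must keep
$\mathrm{duration} \ge 2\,\mathrm{ramp}$ after any shift, no pulse may
straddle the refocusing pulse, and a zero-amplitude scheme cannot be
scaled to a b-value. Sub-femtosecond breakpoint disorder from unit
conversion is clamped to a monotone time axis.

## What the motion model does (and does not) show

`liver_signal()` implements a deliberately small two-compartment model:

$$S(b, M_1) = (1-f)\,e^{-b D_{\mathrm{liver}}} +
  f\,e^{-b D_{\mathrm{blood}}}\,
  \left|\frac{\sin(M_1 v_{\mathrm{blood}})}{M_1 v_{\mathrm{blood}}}\right|,$$

with defaults $f = 0.3$, $D_{\mathrm{blood}} = 1.6$,
$D_{\mathrm{liver}} = 0.95$ µm²/ms — perfusion fraction and diffusivities
typical for liver at a 70 ms echo time — and $v_{\mathrm{blood}} = 20$
mm/s, fast enough that the monopolar $M_1$ ($\approx 5.8$ s/mm at b = 800)
fully dephases the blood pool while $M_1 = 0$ retains it. The sinc factor
is the ballistic-limit orientation average over isotropic plug flow
($\cos\theta$ uniform on $[-1,1]$); the test suite checks it against a
Monte-Carlo orientation average. The blood-velocity distribution of real
vessels is not modelled, nor are pseudo-diffusive IVIM regimes, exchange,
relaxation differences, or cardiac-cycle dependence.

The model reproduces the *mechanism* of the apparent-ADC bias: with the
blood pool dephased the two-point ADC falls near $D_{\mathrm{liver}}$,
with it retained the ADC rises toward the perfusion-weighted mixture
$f D_{\mathrm{blood}} + (1-f) D_{\mathrm{liver}} = 1.145$ µm²/ms
(two-point log-ratio on the biexponential: $\approx 1.11$ µm²/ms between
b = 50 and 800). Only the *direction* of this effect — monopolar ADC below
compensated ADC — is a claim about real livers; in-vivo magnitudes depend
on physiology the model does not contain. Likewise the ballistic
attenuation cannot attribute blood suppression to $M_1$- versus
$M_2$-weighting, which remains an open question of the underlying
physiology.

```{r adc}
model <- liver_model()
mixed_adc_estimate(model)
adc(liver_signal(50, 0, liver_model(v_blood = 0)),
    liver_signal(800, 0, liver_model(v_blood = 0)))
```

`trace_weighted()` and `roi_normalize()` implement the evaluation-side
conventions (arithmetic mean over repetitions, geometric mean over three
orthogonal directions; normalization to the right-lobe monopolar b = 50
signal) so that synthetic ROI pipelines can mirror the in-vivo processing.

## Numerical choices

* Root finds (the compensated $a$, the shift for a target fraction) use
  bisection-class `uniroot` with $10^{-9}$ ms interval tolerance on the
  exact trapezoid moments — never on the rectangular approximation.
* The tuning coefficient uses a *signed* central difference
  ($t_S = \pm 0.01$ ms): the absolute fraction has a kink at the
  compensated point, where a central difference of $|M_1|$ would vanish.
* Waveform CSV files sample at a 10 µs dwell; re-reading one reproduces
  moments to $\sim 10^{-3}$ relative (sampling error). The breakpoint JSON
  format is exact to conversion rounding ($\sim 10^{-13}$).
* Moments are kept signed internally; displays print magnitudes with two
  significant figures below 1 and two decimals above, the convention of
  published moment tables. Machine-readable outputs keep full precision.

## Scope and limitations

The package designs and analyses single-axis spin-echo encodings. It does
not optimize against slew-rate, PNS or acoustic limits, does not model
finite RF pulse durations or oblique multi-axis concomitant cross-terms,
and does not attempt to reproduce numerically optimized waveform shapes
bit-for-bit — the trapezoid construction with equal absolute amplitudes
and 1.3 ms ramps throughout is the package's analytic idealization of
them, which reproduces the published absolute moments to within a few
percent. Image formation, fat saturation and reader studies are out of
scope.
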