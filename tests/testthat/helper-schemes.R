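# Standard schemes used across tests, built once. The 23/10/23 ms geometry
# with 1.3 ms ramps at b = 50 and 800 s/mm^2 is the reference setting.

std <- local({
  acc <- build_acceleration_compensated(side = 23, pause = 10, ramp = 1.3,
                                        target_b = 800)
  list(
    mono800 = build_monopolar(target_b = 800),
    mono50 = build_monopolar(target_b = 50),
    vel800 = build_velocity_compensated(target_b = 800),
    acc = acc,
    s45 = apply_timing_shift(acc$timings, 0.45),
    s95 = apply_timing_shift(acc$timings, 0.95))
})

# independent adaptive-quadrature oracle for the gradient moments: evaluates
# the piecewise-linear waveform by interpolation and integrates G(t) t^k
# segment by segment with stats::integrate
quad_moment <- function(w, k, gamma = GAMMA_PROTON) {
  t <- w$breakpoints; g <- w$values
  f <- function(tt) stats::approx(t, g, xout = tt, ties = "ordered")$y * tt^k
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    if (t[i + 1L] <= t[i]) next
    total <- total + stats::integrate(f, t[i], t[i + 1L],
                                      rel.tol = 1e-12, abs.tol = 0)$value
  }
  gamma * total
}

# random multi-pulse spin-echo scheme with positive ramps (so the waveform
# has no jump discontinuities and interpolation oracles apply)
random_scheme <- function() {
  n_pre <- sample(1:2, 1); n_post <- sample(1:2, 1)
  mk_side <- function(n, t0) {
    ps <- list()
    for (i in seq_len(n)) {
      ramp <- runif(1, 0.2, 1.5)
      dur <- runif(1, 2 * ramp + 0.5, 15)
      ps[[i]] <- trapezoid_pulse(t0, dur, ramp, runif(1, -40, 40))
      t0 <- t0 + dur + runif(1, 0, 2)
    }
    list(pulses = ps, end = t0)
  }
  pre <- mk_side(n_pre, 0)
  pause <- runif(1, 2, 12)
  post <- mk_side(n_post, pre$end + pause)
  encoding_scheme(c(pre$pulses, post$pulses),
                  refocus = pre$end + pause / 2,
                  label = "random")
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
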