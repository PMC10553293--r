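# Exact piecewise-linear moment and b-value engine

test_that("moments of a single rectangle match the gamma*G*tau^k closed forms", {
  # G = 10 mT/m over [0, 10 ms]: M0 = gamma*G*tau, M1 = gamma*G*tau^2/2,
  # M2 = gamma*G*tau^3/3
  w <- new_effective_waveform(c(0, 0, 10e-3, 10e-3),
                              c(0, 1e-5, 1e-5, 0))
  m <- moments(w)
  expect_equal(m$M0, 2.678e8 * 1e-5 * 1e-2, tolerance = 1e-12)   # 26.78 /mm
  expect_equal(m$M1, 2.678e8 * 1e-5 * 1e-4 / 2, tolerance = 1e-12) # 0.1339 s/mm
  expect_equal(m$M2, 2.678e8 * 1e-5 * 1e-6 / 3, tolerance = 1e-12) # 8.927e-4
})

test_that("effective waveform flips pre-refocus polarity only", {
  # all pulses after the 180: identity on amplitudes
  s_post <- encoding_scheme(list(trapezoid_pulse(5, 10, 1, 20)), refocus = 2)
  w <- effective_waveform(s_post)
  expect_equal(max(w$values), 20e-6)
  expect_equal(min(w$values), 0)

  # monopolar: first lobe negated, second unchanged, M0 = 0 (spin echo)
  w <- effective_waveform(std$mono800)
  mid1 <- diffenc:::.eval_waveform(w, 10e-3)
  mid2 <- diffenc:::.eval_waveform(w, 43e-3)
  expect_lt(mid1, 0)
  expect_gt(mid2, 0)
  expect_equal(mid1, -mid2)
  expect_equal(moments(w)$M0, 0, tolerance = 1e-9)

  # velocity-compensated: effective sign pattern (+, -, pause, -, +)
  w <- effective_waveform(std$vel800)
  probe <- diffenc:::.eval_waveform(w, c(5, 17, 39, 50) * 1e-3)
  expect_equal(sign(probe), c(1, -1, -1, 1))

  # a pulse straddling the refocus time is rejected
  expect_error(encoding_scheme(list(trapezoid_pulse(0, 10, 1, 20)), refocus = 5),
               "straddle")
})

test_that("closed-form moments agree with the adaptive-quadrature oracle", {
  set.seed(42)
  for (i in 1:15) {
    w <- effective_waveform(random_scheme())
    m <- moments(w)
    for (k in 0:2) {
      ref <- quad_moment(w, k)
      got <- c(m$M0, m$M1, m$M2)[k + 1]
      scale <- max(abs(ref), GAMMA_PROTON * max(abs(w$values)) *
                     max(w$breakpoints)^(k + 1))
      expect_lt(abs(got - ref) / scale, 1e-8)
    }
  }
})

test_that("moments are linear and b quadratic in a global amplitude factor", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_scheme()
    fac <- runif(1, 0.3, 3)
    m1 <- moments(s); m2 <- moments(scale_amplitude(s, fac))
    expect_equal(m2$M0, fac * m1$M0, tolerance = 1e-12)
    expect_equal(m2$M1, fac * m1$M1, tolerance = 1e-12)
    expect_equal(m2$M2, fac * m1$M2, tolerance = 1e-12)
    expect_equal(bvalue(s, warn = FALSE) * fac^2,
                 bvalue(scale_amplitude(s, fac), warn = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("b-value reproduces the Stejskal-Tanner rectangular closed form", {
  # rectangle pair delta = 23 ms, Delta = 33 ms: b = q^2 (Delta - delta/3)
  s <- build_monopolar(ramp = 0, target_b = 800)
  G <- diffenc:::.mTm_to_Tmm(peak_amplitude(s))
  q <- GAMMA_PROTON * G * 23e-3
  expect_equal(q^2 * (33e-3 - 23e-3 / 3), 800, tolerance = 1e-10)

  # zero waveform
  expect_equal(bvalue(new_effective_waveform(c(0, 1e-3), c(0, 0))), 0)
})

test_that("scale_to_b is exact and errors on a zero-b scheme", {
  s <- std$mono800
  expect_equal(bvalue(scale_to_b(s, 800)), 800, tolerance = 1e-12)
  expect_equal(peak_amplitude(scale_to_b(s, 800)), peak_amplitude(s),
               tolerance = 1e-12)
  s50 <- scale_to_b(s, 50)
  expect_equal(bvalue(s50), 50, tolerance = 1e-10)
  # |M1| scales with sqrt(b): 5.83 -> 1.46 is a factor 4 = sqrt(800/50)
  expect_equal(abs(moments(s50)$M1) * 4, abs(moments(s)$M1), tolerance = 1e-10)
  zero <- encoding_scheme(list(trapezoid_pulse(0, 10, 1, 0)), refocus = 12)
  expect_error(scale_to_b(zero, 800), "zero b-value")
})

test_that("odd-symmetric waveforms with M0 = 0 satisfy M2 = 2*tau*M1", {
  # holds for the whole short/long family (any t_S) and the monopolar pair
  for (tS in c(0, 0.3, 0.8, 1.4)) {
    s <- apply_timing_shift(std$acc$timings, tS)
    m <- moments(s)
    tau <- diffenc:::.s_to_ms(s$total_duration) / 2
    expect_equal(m$M2, 2 * tau * 1e-3 * m$M1,
                 tolerance = 1e-9 * max(1e-3, abs(m$M2)))
  }
  m <- moments(std$mono800)
  expect_equal(m$M2, 56e-3 * m$M1, tolerance = 1e-10)
})

test_that("time-origin translation fixes M1 (for M0 = 0) and shifts M2 by 2*dt*M1", {
  set.seed(11)
  for (i in 1:8) {
    s <- random_scheme()
    w <- effective_waveform(s)
    # remove the position dependence: force M0 = 0 by mirroring the scheme
    # is overkill; instead verify the translation identities directly
    dt <- runif(1, 1e-3, 20e-3)
    w2 <- new_effective_waveform(w$breakpoints + dt, w$values)
    m1 <- moments(w); m2 <- moments(w2)
    expect_equal(m2$M1, m1$M1 + dt * m1$M0, tolerance = 1e-9)
    expect_equal(m2$M2, m1$M2 + 2 * dt * m1$M1 + dt^2 * m1$M0, tolerance = 1e-9)
  }
  # with M0 = 0 (any valid spin-echo scheme) M1 is origin-invariant
  w <- effective_waveform(std$vel800)
  w2 <- new_effective_waveform(w$breakpoints + 7e-3, w$values)
  expect_equal(moments(w2)$M1, moments(w)$M1, tolerance = 1e-12)
})

test_that("concomitant balance is zero for symmetric schemes, positive one-sided", {
  for (s in list(std$mono800, std$mono50, std$vel800, std$acc$scheme,
                 std$s45, std$s95))
    expect_equal(concomitant_balance(s), 0, tolerance = 1e-18)

  one <- encoding_scheme(list(trapezoid_pulse(0, 11.5, 1.3, 30)), refocus = 13)
  A <- 30e-6
  expect_equal(concomitant_balance(one),
               A^2 * (11.5e-3 - 2 * 1.3e-3 + 2 * 1.3e-3 / 3),
               tolerance = 1e-18)

  # G^2 is sign-blind: negating one side does not break the balance
  flipped <- std$mono800
  flipped$pulses[[1]]$amplitude <- -flipped$pulses[[1]]$amplitude
  expect_equal(concomitant_balance(flipped), 0, tolerance = 1e-18)
})

test_that("nonzero M0 triggers a b-value warning but still returns b", {
  one_lobe <- new_effective_waveform(c(0, 0, 10e-3, 10e-3), c(0, 1e-5, 1e-5, 0))
  expect_warning(b <- bvalue(one_lobe), "M0")
  expect_gt(b, 0)
})

test_that("trapezoid invariants are enforced", {
  expect_error(trapezoid_pulse(0, 2, 1.5, 10), "duration")
  expect_error(trapezoid_pulse(0, 2, -0.1, 10), "ramp")
  expect_error(encoding_scheme(list(trapezoid_pulse(0, 10, 1, 5),
                                    trapezoid_pulse(5, 10, 1, 5)),
                               refocus = 30), "overlap")
})
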