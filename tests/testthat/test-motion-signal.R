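# Phase accrual, ballistic-flow attenuation, liver signal model, ADC

test_that("phase is M0*x0 + M1*v + M2*acc/2 and linear in each argument", {
  m <- moments(std$mono800)
  expect_equal(motion_phase(m, motion_state(v = 1)), m$M1)   # ~5.8 rad
  expect_equal(motion_phase(m, motion_state(acc = 2)), m$M2)
  set.seed(5)
  for (i in 1:5) {
    x0 <- rnorm(1); v <- rnorm(1); acc <- rnorm(1); k <- runif(1, 0.1, 4)
    expect_equal(motion_phase(m, motion_state(x0, k * v, acc)) -
                   motion_phase(m, motion_state(x0, 0, acc)),
                 k * m$M1 * v, tolerance = 1e-12)
    expect_equal(motion_phase(m, motion_state(x0, v, acc)),
                 m$M0 * x0 + m$M1 * v + 0.5 * m$M2 * acc, tolerance = 1e-12)
  }
})

test_that("compensated schemes null the phase of the matching motion order", {
  mv <- moments(std$vel800)
  ma <- moments(std$acc$scheme)
  for (v in c(-30, 5, 80)) {
    expect_lt(abs(motion_phase(mv, motion_state(v = v))), 1e-10)
    expect_lt(abs(motion_phase(ma, motion_state(v = v, acc = 10 * v))), 1e-9)
  }
})

test_that("ballistic attenuation is the isotropic plug-flow orientation average", {
  expect_equal(ballistic_attenuation(0, 50), 1)
  expect_equal(ballistic_attenuation(5.8, 0), 1)
  expect_true(all(ballistic_attenuation(seq(0, 10, 0.5), 3) <= 1))
  expect_true(all(ballistic_attenuation(seq(0, 10, 0.5), 3) >= 0))
  # even in M1
  expect_equal(ballistic_attenuation(-2.3, 4), ballistic_attenuation(2.3, 4))
  # sinc decay at large M1*v
  expect_lt(ballistic_attenuation(5.8, 100), 0.002)
  # Monte-Carlo orientation average oracle: mean of cos(M1 v u), u ~ U(-1,1)
  set.seed(2024)
  u <- runif(1e6, -1, 1)
  for (x in c(0.5, 1.46, 2.9)) {
    mc <- abs(mean(cos(x * u)))
    expect_lt(abs(ballistic_attenuation(x, 1) - mc), 1e-3)
  }
})

test_that("two-point ADC inverts monoexponential decay exactly", {
  set.seed(9)
  for (i in 1:10) {
    D <- runif(1, 0.2, 3)                      # um^2/ms
    bl <- runif(1, 0, 200); bh <- bl + runif(1, 200, 1500)
    S <- function(b) exp(-b * D * 1e-3)
    expect_equal(adc(S(bl), S(bh), bl, bh), D, tolerance = 1e-12)
  }
  expect_equal(adc(0.5, 0.5), 0)
  expect_error(adc(-1, 0.5), "positive")
})

test_that("liver signal model reduces correctly and biases the ADC", {
  model <- liver_model(f = 0.3, D_blood = 1.6, D_liver = 0.95, v_blood = 20)
  # f = 0: pure monoexponential tissue decay
  m0 <- liver_model(f = 0, v_blood = 20)
  expect_equal(liver_signal(800, 0, m0), exp(-800 * 0.95e-3))
  # normalization at b -> 0, M1 = 0
  expect_equal(liver_signal(0, 0, model), 1)
  # with the blood pool retained (attenuation 1), the two-point ADC is close
  # to the mixed estimate f*D_blood + (1-f)*D_liver
  mstill <- liver_model(f = 0.3, v_blood = 0)
  a <- adc(liver_signal(50, 0, mstill), liver_signal(800, 0, mstill))
  expect_equal(a, 1.1100, tolerance = 1e-3)
  expect_equal(mixed_adc_estimate(model), 1.145, tolerance = 1e-12)
  expect_equal(mixed_adc_estimate(liver_model(f = 0)), 0.95)
  expect_equal(mixed_adc_estimate(liver_model(f = 1)), 1.6)
  expect_lt(abs(a - mixed_adc_estimate(model)), 0.05)
})

test_that("velocity weighting lowers the apparent ADC (right-lobe bias direction)", {
  # fast blood: fully dephased under the monopolar M1, retained when M1 = 0
  model <- liver_model(f = 0.3, D_blood = 1.6, D_liver = 0.95, v_blood = 20)
  adc_for <- function(scheme50, scheme800) {
    S50 <- liver_signal(50, moments(scheme50)$M1, model)
    S800 <- liver_signal(800, moments(scheme800)$M1, model)
    adc(S50, S800)
  }
  adc_mono <- adc_for(std$mono50, std$mono800)
  adc_vel <- adc_for(scale_to_b(std$vel800, 50), std$vel800)
  expect_lt(adc_mono, adc_vel)
  # monopolar ADC falls near the tissue diffusivity; compensated near the
  # perfusion-weighted mixture
  expect_lt(abs(adc_mono - 0.95), 0.12)
  expect_lt(abs(adc_vel - mixed_adc_estimate(model)), 0.08)
})

test_that("trace-weighted combination: arithmetic over repetitions, geometric over directions", {
  expect_equal(trace_weighted(matrix(3.2, 3, 5)), 3.2)
  expect_equal(trace_weighted(list(1, 4, 16)), 4)
  set.seed(77)
  x <- matrix(runif(15, 0.1, 2), 3, 5)
  expect_equal(trace_weighted(x), prod(rowSums(x) / 5)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(trace_weighted(matrix(c(0, 0, 0, 0, 0, 1, 2, 3, 4, 5), 2, 5,
                                     byrow = TRUE)), 0)
})

test_that("ROI normalization divides by the reference and preserves ratios", {
  expect_equal(roi_normalize(1.0, 1.0), 1)
  expect_equal(roi_normalize(c(0.5, 1.0), 1.0), c(0.5, 1.0))
  set.seed(3)
  r <- runif(1, 0.2, 0.95)          # imposed left/right signal ratio
  right <- runif(20, 0.5, 2); left <- r * right
  norm <- roi_normalize(rbind(left, right), mean(right))
  expect_equal(mean(norm[1, ]) / mean(norm[2, ]), r, tolerance = 1e-12)
  expect_error(roi_normalize(c(1, 2), 0), "positive")
})
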