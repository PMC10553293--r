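# Closed-form expressions for the idealized rectangular-pulse (ramp = 0)
# version of the short/long pulse-pair encoding family. These serve as
# independent oracles for the piecewise-linear moment engine and explain
# the single-parameter tuning behaviour analytically.

#' Rectangular-pulse M1 expression
#'
#' For the rectangular short/long pulse family with effective pattern
#' (+a, -b | pause c | +b, -a) and unit amplitude, the first gradient
#' moment (time origin at encoding start) is proportional to
#' \deqn{(a + b + c)(b - a) - 2ab.}
#' The acceleration-compensated solution is the positive root of this
#' expression under `a + b` fixed. Times may be given in any consistent
#' unit; the result is in that unit squared (multiply by gamma times the
#' amplitude for the physical M1).
#'
#' @param a Short-pulse duration.
#' @param b Long-pulse duration.
#' @param c Pause length.
#' @return The proportional M1 value.
#' @export
rect_m1_poly <- function(a, b, c) (a + b + c) * (b - a) - 2 * a * b

#' Rectangular-pulse M2 polynomial
#'
#' The second gradient moment of the same rectangular family is
#' proportional to the cubic polynomial
#' \deqn{-2a^3 + 2b^3 - 6a^2 b - 3a^2 c + 3b^2 c - 2ab^2 - ac^2 + bc^2 - 2abc,}
#' which factors exactly as `(2a + 2b + c) * rect_m1_poly(a, b, c)` -- the
#' algebraic form of the odd-symmetry identity M2 = T * M1 with T the total
#' encoding duration.
#'
#' @inheritParams rect_m1_poly
#' @return The proportional M2 value.
#' @export
m2_rect_poly <- function(a, b, c) {
  -2 * a^3 + 2 * b^3 - 6 * a^2 * b - 3 * a^2 * c + 3 * b^2 * c -
    2 * a * b^2 - a * c^2 + b * c^2 - 2 * a * b * c
}

#' Closed-form moments of the rectangular pulse family
#'
#' Exact M1 and M2 (signed, time origin at encoding start) of the
#' rectangular short/long pulse-pair encoding with timing shift `t_S`,
#' evaluated from the closed-form polynomials rather than the piecewise
#' integration engine.
#'
#' @param a,b,c Timings in ms (short pulse, long pulse, pause).
#' @param t_S Timing shift (ms).
#' @param amplitude Gradient amplitude (mT/m).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return List with `M1` (s/mm) and `M2` (s^2/mm).
#' @export
rect_moments <- function(a, b, c, t_S = 0, amplitude = 1, gamma = GAMMA_PROTON) {
  a_s <- .ms_to_s(a + t_S); b_s <- .ms_to_s(b - t_S); c_s <- .ms_to_s(c)
  gA <- gamma * .mTm_to_Tmm(amplitude)
  list(M1 = gA * rect_m1_poly(a_s, b_s, c_s),
       M2 = gA * m2_rect_poly(a_s, b_s, c_s))
}

#' Rectangular scheme for the short/long family
#'
#' Convenience constructor for the ramp-free (rectangular) version of the
#' short/long pulse-pair encoding, used to cross-check the closed forms
#' against the numeric engine.
#'
#' @inheritParams rect_moments
#' @param target_b Optional b-value to scale to (s/mm^2).
#' @return An [encoding_scheme()].
#' @export
rect_accel_scheme <- function(a, b, c, t_S = 0, target_b = NULL) {
  .accel_scheme(a + t_S, b - t_S, c, ramp_ms = 0, target_b = target_b,
                label = "rectangular short/long pair")
}

#' Solve the rectangular acceleration-compensated timing
#'
#' Positive root of `rect_m1_poly(a, side - a, c)` in `a`: the closed-form
#' quadratic solution `d^2 + 2(side + c) d - (side^2 - ... )`, solved here
#' directly for `d = b - a`.
#'
#' @param side Per-side duration `a + b` (ms).
#' @param c Pause (ms).
#' @return List with solved `a` and `b` (ms).
#' @export
rect_accel_solution <- function(side = 23, c = 10) {
  # (side + c) d = 2ab = (side^2 - d^2)/2  with d = b - a
  # => d^2 + 2 (side + c) d - side^2 = 0
  d <- -(side + c) + sqrt((side + c)^2 + side^2)
  list(a = (side - d) / 2, b = (side + d) / 2)
}

#' First-order coefficients of the moments in the timing shift
#'
#' Exact derivatives of the rectangular closed forms at `t_S = 0`:
#' `dM1/dt_S = -2 gamma G (2b + c)` and `dM2/dt_S = T * dM1/dt_S` with
#' `T = 2a + 2b + c`, so the M2-to-M1 coefficient ratio equals the total
#' encoding duration. The relative coefficient divides by the monopolar
#' reference moment at the same b-value, giving the per-ms tuning rate of
#' the residual fractions.
#'
#' @param a,b,c Timings (ms) at the compensated solution.
#' @param b_diff Diffusion weighting fixing the amplitude (s/mm^2).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @return List with `dM1_dtS` ((s/mm)/ms), `dM2_dtS` ((s^2/mm)/ms),
#'   `ratio_ms` (ms, equal to `2a + 2b + c`) and `relative_per_ms`
#'   (1/ms, the slope of |M1|/M1max in t_S).
#' @export
linear_coefficients <- function(a, b, c, b_diff = 800, gamma = GAMMA_PROTON) {
  sch <- rect_accel_scheme(a, b, c, target_b = b_diff)
  G <- .mTm_to_Tmm(peak_amplitude(sch))                       # T/mm
  dM1 <- -2 * gamma * G * .ms_to_s(2 * b + c)                 # per s of t_S
  Tt <- .ms_to_s(2 * a + 2 * b + c)
  ref <- build_monopolar(pre = a + b, pause = c, post = a + b, ramp = 0,
                         target_b = b_diff)
  M1max <- abs(moments(ref)$M1)
  list(dM1_dtS = dM1 * 1e-3,                                  # per ms
       dM2_dtS = Tt * dM1 * 1e-3,
       ratio_ms = .s_to_ms(Tt),
       relative_per_ms = abs(dM1) * 1e-3 / M1max)
}

#' Tuning coefficient of the trapezoid scheme by finite differences
#'
#' Central-difference slope of the signed residual fraction M1/M1max with
#' respect to the timing shift, evaluated at `t_S = 0` on the full
#' trapezoid scheme (amplitude re-solved for the target b at every shift).
#' The signed moment is used because |M1| has a kink at the compensated
#' point. For the 23/10/23 ms geometry with 1.3 ms ramps this is
#' approximately 0.35 per ms, independent of the b-value.
#'
#' @param timings An [accel_timings()] at the compensated solution.
#' @param h Half-step of the central difference (ms).
#' @return Slope of the residual fraction per ms of t_S (1/ms).
#' @export
relative_coefficient_trapezoid <- function(timings, h = 0.01) {
  stopifnot(inherits(timings, "accel_timings"))
  ref <- build_monopolar(pre = timings$a + timings$b, pause = timings$c,
                         post = timings$a + timings$b, ramp = timings$ramp,
                         target_b = timings$target_b)
  M1max <- moments(ref)$M1
  f <- function(t_S) moments(apply_timing_shift(timings, t_S))$M1 / M1max
  abs(f(h) - f(-h)) / (2 * h)
}
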