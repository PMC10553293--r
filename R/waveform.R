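#' Effective gradient waveform of a spin-echo encoding
#'
#' Constructs the exact piecewise-linear effective gradient of a scheme: the
#' polarity of every pulse played before the refocusing pulse is negated, so
#' that phase behaviour after the echo can be computed by straight
#' integration. The time origin is placed at the start of the first pulse
#' (the start of the diffusion encoding), and this convention is recorded in
#' the `origin` field.
#'
#' @param scheme An [encoding_scheme()].
#' @return An object of class `effective_waveform` with fields
#'   `breakpoints` (s), `values` (T/mm), `origin` (convention marker) and
#'   `refocus` (s, relative to the origin).
#' @export
effective_waveform <- function(scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  t <- numeric(0); g <- numeric(0)
  for (p in scheme$pulses) {
    amp <- if (p$start + p$duration <= scheme$refocus + 1e-12) -p$amplitude else p$amplitude
    bp <- .pulse_breakpoints(p, amplitude = amp)
    t <- c(t, bp$t); g <- c(g, bp$g)
  }
  # adjacent pulses can disagree about their shared instant by ~1e-17 s
  # through unit-conversion rounding; clamp to a monotone time axis
  t <- cummax(t)
  t0 <- t[1L]
  new_effective_waveform(t - t0, g, refocus = scheme$refocus - t0)
}

#' Construct an effective waveform from explicit breakpoints
#'
#' Low-level constructor for a piecewise-linear effective gradient. The
#' waveform must start and end at zero gradient.
#'
#' @param breakpoints Non-decreasing breakpoint times (s). Repeated times
#'   encode jump discontinuities of rectangular pulses.
#' @param values Effective gradient at the breakpoints (T/mm).
#' @param refocus Optional refocusing-pulse time (s) relative to the same
#'   origin; `NA` if unknown.
#' @param origin Time-origin convention marker.
#' @return An `effective_waveform` object.
#' @export
new_effective_waveform <- function(breakpoints, values, refocus = NA_real_,
                                   origin = "encoding_start") {
  stopifnot(length(breakpoints) == length(values), length(breakpoints) >= 2)
  if (is.unsorted(breakpoints)) stop("breakpoints must be non-decreasing")
  if (abs(values[1L]) > 0 || abs(values[length(values)]) > 0)
    stop("effective waveform must start and end at zero gradient")
  structure(list(breakpoints = as.numeric(breakpoints),
                 values = as.numeric(values),
                 refocus = refocus, origin = origin),
            class = "effective_waveform")
}

#' @export
print.effective_waveform <- function(x, ...) {
  cat(sprintf("<effective_waveform> %d breakpoints over %.2f ms (origin: %s)\n",
              length(x$breakpoints), .s_to_ms(max(x$breakpoints)), x$origin))
  invisible(x)
}

#' Gradient moments and b-value of a waveform
#'
#' Computes the zeroth, first and second gradient moments
#' \deqn{M_n = \gamma \int G_{\mathrm{eff}}(t)\, t^n \, dt}
#' of the effective waveform by exact closed-form integration of the
#' polynomial integrand over each linear segment (no numerical quadrature),
#' together with the b-value. `M0` relates to position sensitivity, `M1` to
#' velocity (a velocity-compensated encoding has `M1 = 0`) and `M2` to
#' acceleration. Signed values are returned; printed tables usually report
#' magnitudes.
#'
#' @param x An `effective_waveform` or an `encoding_scheme` (converted via
#'   [effective_waveform()]).
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param ... Passed to methods.
#' @return An object of class `moment_set`: list with `M0` (1/mm), `M1`
#'   (s/mm), `M2` (s^2/mm), `b` (s/mm^2) and `gamma`.
#' @examples
#' s <- build_monopolar(target_b = 800)
#' moments(s)
#' @export
moments <- function(x, ...) UseMethod("moments")

#' @rdname moments
#' @export
moments.encoding_scheme <- function(x, gamma = GAMMA_PROTON, ...) {
  moments(effective_waveform(x), gamma = gamma)
}

#' @rdname moments
#' @export
moments.effective_waveform <- function(x, gamma = GAMMA_PROTON, ...) {
  t <- x$breakpoints; g <- x$values
  M <- c(0, 0, 0)
  for (i in seq_len(length(t) - 1L)) {
    t0 <- t[i]; t1 <- t[i + 1L]; h <- t1 - t0
    if (h <= 0) next
    slope <- (g[i + 1L] - g[i]) / h
    A <- g[i] - slope * t0                    # G(t) = A + B t on the segment
    B <- slope
    for (k in 0:2) {
      M[k + 1L] <- M[k + 1L] +
        A * (t1^(k + 1) - t0^(k + 1)) / (k + 1) +
        B * (t1^(k + 2) - t0^(k + 2)) / (k + 2)
    }
  }
  structure(list(M0 = gamma * M[1L], M1 = gamma * M[2L], M2 = gamma * M[3L],
                 b = bvalue(x, gamma = gamma, warn = FALSE), gamma = gamma),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set>  M0 = %.4g /mm  |M1| = %.4g s/mm  |M2| = %.4g s^2/mm  b = %.4g s/mm^2\n",
              x$M0, abs(x$M1), abs(x$M2), x$b))
  invisible(x)
}

#' b-value of an effective waveform
#'
#' Diffusion weighting \eqn{b = \int_0^T q(t)^2 dt} with the dephasing
#' trajectory \eqn{q(t) = \gamma \int_0^t G_{\mathrm{eff}}(t') dt'}. Since
#' the effective gradient is piecewise linear, q is piecewise quadratic and
#' the integral of q^2 is evaluated exactly segment by segment (quartic
#' power rule). A non-vanishing M0 (no echo forms) triggers a warning but
#' the integral is still returned.
#'
#' @inheritParams moments
#' @param warn Warn when the waveform has a non-vanishing zeroth moment.
#' @return b-value in s/mm^2 (>= 0).
#' @export
bvalue <- function(x, ...) UseMethod("bvalue")

#' @rdname bvalue
#' @export
bvalue.encoding_scheme <- function(x, gamma = GAMMA_PROTON, warn = TRUE, ...) {
  bvalue(effective_waveform(x), gamma = gamma, warn = warn)
}

#' @rdname bvalue
#' @export
bvalue.effective_waveform <- function(x, gamma = GAMMA_PROTON, warn = TRUE, ...) {
  t <- x$breakpoints; g <- x$values
  q <- 0; b <- 0; qscale <- 0
  for (i in seq_len(length(t) - 1L)) {
    t0 <- t[i]; t1 <- t[i + 1L]; h <- t1 - t0
    if (h <= 0) next
    slope <- (g[i + 1L] - g[i]) / h
    # q(t0 + s) = c0 + c1 s + c2 s^2 on [0, h]
    c0 <- q; c1 <- gamma * g[i]; c2 <- gamma * slope / 2
    b <- b + c0^2 * h + c0 * c1 * h^2 + (c1^2 + 2 * c0 * c2) * h^3 / 3 +
      c1 * c2 * h^4 / 2 + c2^2 * h^5 / 5
    q <- q + c1 * h + c2 * h^2
    qscale <- max(qscale, abs(q))
  }
  if (warn && qscale > 0 && abs(q) > 1e-9 * qscale)
    warning("waveform has non-vanishing M0 (no echo forms); b-value returned anyway")
  b
}

#' Scale a scheme's amplitude to reach a target b-value
#'
#' b is quadratic in a global amplitude factor, so the exact factor is
#' `sqrt(target_b / current_b)`; no iteration is needed.
#'
#' @param scheme An [encoding_scheme()].
#' @param target_b Target diffusion weighting (s/mm^2), > 0.
#' @return The scheme with all amplitudes rescaled.
#' @export
scale_to_b <- function(scheme, target_b) {
  stopifnot(inherits(scheme, "encoding_scheme"), target_b > 0)
  b0 <- bvalue(scheme, warn = FALSE)
  if (b0 <= 0) stop("scheme has zero b-value at current amplitude; cannot scale")
  scale_amplitude(scheme, sqrt(target_b / b0))
}

#' First-order concomitant-field balance of a scheme
#'
#' Concomitant (Maxwell) fields scale with the square of the applied
#' gradient, and their phase is refocused when the integral of G^2 before
#' the 180 degree pulse equals the integral after it. This returns
#' \deqn{\int_{\mathrm{start}}^{\mathrm{180}} G(t)^2 dt -
#'       \int_{\mathrm{180}}^{\mathrm{end}} G(t)^2 dt}
#' on the physical (unflipped) waveform, in (T/mm)^2 s; zero indicates
#' first-order concomitant-phase balance. Symmetric schemes are balanced by
#' construction.
#'
#' @param scheme An [encoding_scheme()].
#' @return Signed imbalance in T^2 s/mm^2.
#' @export
concomitant_balance <- function(scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  seg_int <- function(p) {
    # integral of G^2 over one trapezoid: two ramps + flat top
    flat <- p$duration - 2 * p$ramp
    p$amplitude^2 * (flat + 2 * p$ramp / 3)
  }
  pre <- 0; post <- 0
  for (p in scheme$pulses) {
    if (p$start + p$duration <= scheme$refocus + 1e-12) pre <- pre + seg_int(p)
    else post <- post + seg_int(p)
  }
  pre - post
}
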