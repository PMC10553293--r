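#' Gyromagnetic ratio of the proton
#'
#' Default gyromagnetic ratio used throughout the package, in rad/s/T.
#' @export
GAMMA_PROTON <- 2.678e8

# unit conversions: user interfaces speak ms and mT/m, internals are SI
# (seconds and T/mm; 1 mT/m = 1e-6 T/mm)
.ms_to_s <- function(x) x * 1e-3
.s_to_ms <- function(x) x * 1e3
.mTm_to_Tmm <- function(x) x * 1e-6
.Tmm_to_mTm <- function(x) x * 1e6

#' Trapezoidal gradient pulse
#'
#' A single gradient lobe with linear ramps. `duration` is the total pulse
#' length including both ramps, so the flat top lasts `duration - 2 * ramp`.
#' `ramp = 0` gives an idealized rectangular pulse.
#'
#' @param start Start time of the pulse (ms).
#' @param duration Total duration including both ramps (ms).
#' @param ramp Ramp (rise/fall) time (ms), `>= 0` and `<= duration / 2`.
#' @param amplitude Signed plateau amplitude (mT/m).
#' @return An object of class `trapezoid_pulse`. Fields are stored in SI
#'   units (seconds, T/mm).
#' @examples
#' trapezoid_pulse(start = 0, duration = 23, ramp = 1.3, amplitude = 30)
#' @export
trapezoid_pulse <- function(start, duration, ramp, amplitude) {
  stopifnot(is.numeric(start), is.numeric(duration), is.numeric(ramp),
            is.numeric(amplitude), is.finite(amplitude))
  if (ramp < 0) stop("ramp must be >= 0")
  if (duration < 2 * ramp) stop("duration must be >= 2 * ramp")
  structure(
    list(start = .ms_to_s(start), duration = .ms_to_s(duration),
         ramp = .ms_to_s(ramp), amplitude = .mTm_to_Tmm(amplitude)),
    class = "trapezoid_pulse")
}

#' @export
print.trapezoid_pulse <- function(x, ...) {
  cat(sprintf("<trapezoid_pulse> start %.3f ms, duration %.3f ms, ramp %.3f ms, amplitude %.3f mT/m\n",
              .s_to_ms(x$start), .s_to_ms(x$duration), .s_to_ms(x$ramp),
              .Tmm_to_mTm(x$amplitude)))
  invisible(x)
}

# breakpoint representation of one pulse; zero-duration segments encode the
# vertical edges of a rectangular (ramp = 0) pulse
.pulse_breakpoints <- function(p, amplitude = p$amplitude) {
  if (p$ramp > 0 && p$duration > 2 * p$ramp) {
    t <- p$start + c(0, p$ramp, p$duration - p$ramp, p$duration)
    g <- c(0, amplitude, amplitude, 0)
  } else if (p$ramp > 0) { # triangle
    t <- p$start + c(0, p$ramp, p$duration)
    g <- c(0, amplitude, 0)
  } else {
    t <- p$start + c(0, 0, p$duration, p$duration)
    g <- c(0, amplitude, amplitude, 0)
  }
  # guard against sub-femtosecond rounding when a flat top degenerates
  list(t = cummax(t), g = g)
}

#' Spin-echo diffusion encoding scheme
#'
#' An ordered set of trapezoidal gradient pulses on one axis, played around
#' an (instantaneous) 180 degree refocusing pulse at `refocus`. Pulses must
#' be non-overlapping, time-ordered, and must not straddle the refocusing
#' pulse.
#'
#' @param pulses List of [trapezoid_pulse()] objects.
#' @param refocus Time of the refocusing pulse (ms).
#' @param total_duration Total encoding duration (ms); defaults to the end
#'   of the last pulse.
#' @param label Human-readable scheme name.
#' @return An object of class `encoding_scheme`.
#' @export
encoding_scheme <- function(pulses, refocus, total_duration = NULL, label = "scheme") {
  stopifnot(length(pulses) >= 1)
  if (!all(vapply(pulses, inherits, logical(1), "trapezoid_pulse")))
    stop("all pulses must be trapezoid_pulse objects")
  starts <- vapply(pulses, function(p) p$start, numeric(1))
  pulses <- pulses[order(starts)]
  starts <- sort(starts)
  ends <- vapply(pulses, function(p) p$start + p$duration, numeric(1))
  if (any(starts[-1] < ends[-length(ends)] - 1e-12))
    stop("pulses overlap in time")
  refocus_s <- .ms_to_s(refocus)
  straddle <- starts < refocus_s - 1e-12 & ends > refocus_s + 1e-12
  if (any(straddle))
    stop("invalid scheme: a pulse straddles the refocusing pulse")
  total_s <- if (is.null(total_duration)) max(ends) else .ms_to_s(total_duration)
  if (total_s < max(ends) - 1e-12)
    stop("total_duration is shorter than the last pulse")
  structure(list(pulses = pulses, refocus = refocus_s,
                 total_duration = total_s, label = label),
            class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme> \"%s\": %d pulses, refocus at %.2f ms, duration %.2f ms\n",
              x$label, length(x$pulses), .s_to_ms(x$refocus),
              .s_to_ms(x$total_duration)))
  for (p in x$pulses) print(p)
  invisible(x)
}

#' Rescale all pulse amplitudes of a scheme by a common factor
#'
#' All pulses in a scheme share one absolute amplitude; only polarity
#' differs. Scaling preserves polarity pattern and timing.
#'
#' @param scheme An [encoding_scheme()].
#' @param factor Dimensionless amplitude factor.
#' @return The rescaled scheme.
#' @export
scale_amplitude <- function(scheme, factor) {
  scheme$pulses <- lapply(scheme$pulses, function(p) {
    p$amplitude <- p$amplitude * factor
    p
  })
  scheme
}

#' Peak gradient amplitude of a scheme
#'
#' @param scheme An [encoding_scheme()].
#' @return Maximum absolute pulse amplitude in mT/m.
#' @export
peak_amplitude <- function(scheme) {
  .Tmm_to_mTm(max(abs(vapply(scheme$pulses, function(p) p$amplitude, numeric(1)))))
}
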