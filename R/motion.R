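# Signal behaviour of moving spins under the encodings: phase accrual,
# ballistic-flow (IVIM-type) attenuation, a two-compartment liver model,
# two-point ADC, and the image-combination rules used for evaluation.

#' Motion state of a spin
#'
#' @param x0 Initial position (mm).
#' @param v Constant velocity (mm/s).
#' @param acc Constant acceleration (mm/s^2).
#' @return An object of class `motion_state`.
#' @export
motion_state <- function(x0 = 0, v = 0, acc = 0) {
  stopifnot(is.finite(x0), is.finite(v), is.finite(acc))
  structure(list(x0 = x0, v = v, acc = acc), class = "motion_state")
}

#' Phase accrued by a uniformly accelerating spin
#'
#' Taylor-expanding the spin trajectory `x(t) = x0 + v t + acc t^2 / 2`
#' against the gradient-moment definitions gives the net phase
#' \deqn{\phi = M_0 x_0 + M_1 v + \tfrac{1}{2} M_2 \, acc} in radians.
#' Velocity-compensated encodings (M1 = 0) null the velocity term;
#' acceleration-compensated encodings (M1 = M2 = 0) null both.
#'
#' @param m A `moment_set` from [moments()].
#' @param s A [motion_state()].
#' @return Phase in radians.
#' @export
motion_phase <- function(m, s) {
  stopifnot(inherits(m, "moment_set"), inherits(s, "motion_state"))
  m$M0 * s$x0 + m$M1 * s$v + 0.5 * m$M2 * s$acc
}

#' Ballistic-flow attenuation factor
#'
#' In the ballistic IVIM limit blood does not change direction during the
#' encoding, so each vessel segment contributes a phase `M1 * v * cos(theta)`.
#' Averaging over isotropically oriented segments (plug flow, cos(theta)
#' uniform on [-1, 1]) yields the attenuation
#' \deqn{|\sin(M_1 v) / (M_1 v)|,} equal to 1 when `M1 * v = 0` and
#' decaying toward 0 for strong velocity weighting.
#'
#' @param M1 First gradient moment (s/mm), signed or absolute.
#' @param speed Blood speed (mm/s), >= 0.
#' @return Attenuation factor in `[0, 1]`.
#' @export
ballistic_attenuation <- function(M1, speed) {
  stopifnot(all(speed >= 0))
  x <- M1 * speed
  ifelse(abs(x) < 1e-8, 1 - x^2 / 6, abs(sin(x) / x))
}

#' Two-compartment liver signal model
#'
#' @param f Perfusion (blood) signal fraction at the echo time.
#' @param D_blood Blood diffusivity (um^2/ms).
#' @param D_liver Liver tissue diffusivity (um^2/ms).
#' @param v_blood Characteristic blood speed (mm/s).
#' @return An object of class `liver_model`.
#' @export
liver_model <- function(f = 0.3, D_blood = 1.6, D_liver = 0.95, v_blood = 20) {
  stopifnot(f >= 0, f <= 1, D_blood > 0, D_liver > 0, v_blood >= 0)
  structure(list(f = f, D_blood = D_blood, D_liver = D_liver,
                 v_blood = v_blood), class = "liver_model")
}

# b [s/mm^2] * D [um^2/ms] -> dimensionless exponent (1 um^2/ms = 1e-3 mm^2/s)
.bD <- function(b, D) b * D * 1e-3

#' Normalized liver signal under an encoding
#'
#' Two-compartment ballistic IVIM model:
#' \deqn{S(b, M_1) = (1 - f) e^{-b D_{liver}} +
#'       f e^{-b D_{blood}} \, A(M_1, v_{blood})}
#' with `A` the [ballistic_attenuation()]. Velocity weighting dephases the
#' flowing blood pool; compensated encodings retain it, which raises the
#' low-b signal and thereby the apparent ADC.
#'
#' @param b Diffusion weighting (s/mm^2).
#' @param M1 First gradient moment of the encoding (s/mm).
#' @param model A [liver_model()].
#' @return Normalized signal (1 at `b = 0`, `M1 = 0`).
#' @export
liver_signal <- function(b, M1, model) {
  stopifnot(inherits(model, "liver_model"))
  (1 - model$f) * exp(-.bD(b, model$D_liver)) +
    model$f * exp(-.bD(b, model$D_blood)) *
      ballistic_attenuation(M1, model$v_blood)
}

#' Two-point apparent diffusion coefficient
#'
#' Log-ratio ADC from a signal pair at two b-values:
#' \deqn{ADC = \ln(S_{low} / S_{high}) / (b_{high} - b_{low}),}
#' converted to um^2/ms.
#'
#' @param S_low,S_high Signals at the lower/higher b-value (> 0).
#' @param b_low,b_high The two diffusion weightings (s/mm^2).
#' @return ADC in um^2/ms.
#' @export
adc <- function(S_low, S_high, b_low = 50, b_high = 800) {
  if (any(S_low <= 0) || any(S_high <= 0))
    stop("undefined ADC: signals must be positive")
  stopifnot(b_high > b_low)
  log(S_low / S_high) / (b_high - b_low) * 1e3   # mm^2/s -> um^2/ms
}

#' Perfusion-weighted mixed ADC estimate
#'
#' First-order estimate of the apparent ADC when the blood pool is not
#' attenuated: `f * D_blood + (1 - f) * D_liver`.
#'
#' @param model A [liver_model()].
#' @return ADC estimate in um^2/ms.
#' @export
mixed_adc_estimate <- function(model) {
  stopifnot(inherits(model, "liver_model"))
  model$f * model$D_blood + (1 - model$f) * model$D_liver
}

#' Trace-weighted image combination
#'
#' Averages the repetitions within each diffusion direction arithmetically,
#' then combines the per-direction images by their geometric mean. A
#' direction mean of zero yields a combined value of zero (not an error).
#'
#' @param signals Numeric matrix (directions x repetitions) or a list of
#'   per-direction repetition vectors; values must be non-negative.
#' @return The combined trace-weighted signal (scalar).
#' @export
trace_weighted <- function(signals) {
  if (is.list(signals)) dir_means <- vapply(signals, mean, numeric(1))
  else if (is.matrix(signals)) dir_means <- rowMeans(signals)
  else dir_means <- mean(signals)
  if (any(dir_means < 0)) stop("signals must be non-negative")
  if (any(dir_means == 0)) return(0)
  exp(mean(log(dir_means)))
}

#' Normalize ROI signals to a reference
#'
#' Element-wise division by a reference value, e.g. the mean signal of the
#' right liver lobe in the monopolar low-b image.
#'
#' @param mean_signals Numeric vector/matrix of per-ROI, per-scheme means.
#' @param reference Positive reference signal.
#' @return `mean_signals / reference`.
#' @export
roi_normalize <- function(mean_signals, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stop("reference must be a single positive value")
  mean_signals / reference
}
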