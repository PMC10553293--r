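# Run configuration: which schemes to build, at which b-values, and where
# to write results. Configs are JSON or YAML; missing fields fall back to
# the defaults below, which mirror the 23/10/23 ms, 1.3 ms ramp geometry
# at b = 50 and 800 s/mm^2.

#' Default run configuration
#'
#' Five encoding schemes (monopolar, velocity-compensated,
#' acceleration-compensated, and two partially compensated variants at
#' t_S = 0.45 and 0.95 ms) on the 23/10/23 ms geometry with 1.3 ms ramps,
#' at b = 50 and 800 s/mm^2.
#'
#' @return A `run_config` list with fields `schemes`, `b_values`,
#'   `dwell_us`, `out_dir`, `log_level`, `model`.
#' @export
default_run_config <- function() {
  structure(list(
    schemes = list(
      list(type = "monopolar", label = "monopolar",
           pre_ms = 23, pause_ms = 10, post_ms = 23, ramp_ms = 1.3),
      list(type = "velocity", label = "velocity-compensated",
           pulse_ms = 11.5, pause_ms = 10, ramp_ms = 1.3),
      list(type = "acceleration", label = "acceleration-compensated",
           side_ms = 23, pause_ms = 10, ramp_ms = 1.3),
      list(type = "shifted", label = "84%-compensated",
           side_ms = 23, pause_ms = 10, ramp_ms = 1.3, t_shift_ms = 0.45),
      list(type = "shifted", label = "67%-compensated",
           side_ms = 23, pause_ms = 10, ramp_ms = 1.3, t_shift_ms = 0.95)),
    b_values = c(50, 800),
    dwell_us = 10,
    out_dir = ".",
    log_level = "info",
    model = list(f = 0.3, D_blood = 1.6, D_liver = 0.95, v_blood = 20)),
    class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Fields absent from the file are filled from [default_run_config()].
#'
#' @param path Config file (`.json`, `.yaml` or `.yml`).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A `run_config` list.
#' @return `cfg`, invisibly classed, or an error.
#' @export
validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$b_values) || any(cfg$b_values <= 0))
    stop("invalid config: b_values must be positive")
  if (!is.numeric(cfg$dwell_us) || cfg$dwell_us <= 0)
    stop("invalid config: dwell_us must be positive")
  for (d in cfg$schemes)
    if (is.null(d$type) ||
        !d$type %in% c("monopolar", "velocity", "acceleration", "shifted"))
      stop("invalid config: unknown scheme type '", d$type %||% "<missing>", "'")
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a scheme from a descriptor
#'
#' Descriptor types: `monopolar` (`pre_ms`, `pause_ms`, `post_ms`,
#' `ramp_ms`), `velocity` (`pulse_ms`, `pause_ms`, `ramp_ms`),
#' `acceleration` (`side_ms`, `pause_ms`, `ramp_ms`) and `shifted` (as
#' `acceleration` plus `t_shift_ms`). `b_s_per_mm2` in the descriptor
#' overrides `target_b`.
#'
#' @param desc Descriptor list (see [default_run_config()] for examples).
#' @param target_b Diffusion weighting (s/mm^2).
#' @return List with `scheme` (an [encoding_scheme()]), `timings`
#'   ([accel_timings()] or `NULL`) and `pause_ms`.
#' @export
build_scheme <- function(desc, target_b = 800) {
  b <- desc$b_s_per_mm2 %||% target_b
  ramp <- desc$ramp_ms %||% 1.3
  pause <- desc$pause_ms %||% 10
  out <- switch(desc$type,
    monopolar = list(
      scheme = build_monopolar(desc$pre_ms %||% 23, pause,
                               desc$post_ms %||% desc$pre_ms %||% 23,
                               ramp, target_b = b),
      timings = NULL),
    velocity = list(
      scheme = build_velocity_compensated(desc$pulse_ms %||% 11.5, ramp,
                                          pause, target_b = b),
      timings = NULL),
    acceleration = {
      acc <- build_acceleration_compensated(desc$side_ms %||% 23, pause,
                                            ramp, target_b = b)
      list(scheme = acc$scheme, timings = acc$timings)
    },
    shifted = {
      acc <- build_acceleration_compensated(desc$side_ms %||% 23, pause,
                                            ramp, target_b = b)
      list(scheme = apply_timing_shift(acc$timings, desc$t_shift_ms %||% 0,
                                       target_b = b),
           timings = acc$timings)
    },
    stop("unknown scheme type: ", desc$type))
  if (!is.null(desc$label)) out$scheme$label <- desc$label
  out$pause_ms <- pause
  out
}
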