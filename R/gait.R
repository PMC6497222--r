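#' Gait parameters for frequency-to-speed mapping
#'
#' Holds the stride geometry and dynamic-similarity limits that convert a
#' vibration frequency into the running speed that would excite it. One
#' footfall per step drives the body once per step; with symmetric gaits the
#' stride (same-foot return) is twice the step. The default `"stride"`
#' convention maps speed as `v = f * stride_length`; `"step"` uses the step
#' rate instead (`v = f * step_length`), for gaits treated with left and
#' right feet out of phase.
#'
#' @param step_length Step length in m (distance between successive
#'   footfalls of alternate feet).
#' @param stride_length Stride length in m; default `2 * step_length`.
#' @param froude_max Dimensionless Froude-number ceiling `v^2 / (g h)` for
#'   feasible running speed (cursorial bipeds are typically bounded well
#'   below 20).
#' @param hip_height Hip height `h` in m; required for [froude_max_speed()].
#' @param gravity Gravitational acceleration, m/s^2.
#' @param excitation `"stride"` (default) or `"step"`: which cycle rate the
#'   footfall forcing is taken at.
#' @return An object of class `gait_params`.
#' @export
#' @examples
#' caudipteryx_gait()
gait_params <- function(step_length, stride_length = 2 * step_length,
                        froude_max = 17, hip_height = NULL, gravity = 9.81,
                        excitation = c("stride", "step")) {
  excitation <- match.arg(excitation)
  vals <- c(step_length = step_length, stride_length = stride_length,
    froude_max = froude_max, gravity = gravity)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all gait parameters must be finite and positive",
      class = "flapmode_validation_error")
  }
  if (stride_length < step_length) {
    rlang::abort("stride_length must be >= step_length",
      class = "flapmode_validation_error")
  }
  if (!is.null(hip_height) && (!is.finite(hip_height) || hip_height <= 0)) {
    rlang::abort("hip_height must be positive", class = "flapmode_validation_error")
  }
  structure(list(step_length = step_length, stride_length = stride_length,
    froude_max = froude_max, hip_height = hip_height, gravity = gravity,
    excitation = excitation), class = "gait_params")
}

#' @export
print.gait_params <- function(x, ...) {
  cat("<gait_params> step ", x$step_length, " m, stride ", x$stride_length,
    " m, Fr_max ", x$froude_max,
    if (!is.null(x$hip_height)) paste0(", hip ", x$hip_height, " m") else "",
    ", ", x$excitation, " convention\n", sep = "")
  invisible(x)
}

gait_cycle_length <- function(gait) {
  if (gait$excitation == "stride") gait$stride_length else gait$step_length
}

#' Convert between excitation frequency and running speed
#'
#' A pure unit conversion: at speed `v` the footfall cycle repeats
#' `v / cycle_length` times per second, so a mode at frequency `f` Hz is
#' resonant at `v = f * cycle_length` (cycle length = stride by default, see
#' [gait_params()]). The two directions are exact inverses.
#'
#' @param f Frequency in Hz (non-negative).
#' @param v Speed in m/s (non-negative).
#' @param gait A [gait_params()].
#' @return Speed in m/s, or frequency in Hz.
#' @export
#' @examples
#' speed_from_frequency(1.92, caudipteryx_gait())  # ~2 m/s
speed_from_frequency <- function(f, gait) {
  if (any(!is.finite(f)) || any(f < 0)) {
    rlang::abort("frequency must be non-negative", class = "flapmode_validation_error")
  }
  f * gait_cycle_length(gait)
}

#' @rdname speed_from_frequency
#' @export
frequency_from_speed <- function(v, gait) {
  if (any(!is.finite(v)) || any(v < 0)) {
    rlang::abort("speed must be non-negative", class = "flapmode_validation_error")
  }
  v / gait_cycle_length(gait)
}

#' Froude-number speed ceiling
#'
#' The maximum dynamically plausible running speed
#' `v_max = sqrt(Fr_max * g * h)`, from the Froude number `Fr = v^2 / (g h)`
#' used to compare gaits across animals of different size.
#'
#' @param gait A [gait_params()] with `hip_height` set.
#' @return Speed in m/s.
#' @export
#' @examples
#' froude_max_speed(caudipteryx_gait())  # ~8 m/s
froude_max_speed <- function(gait) {
  if (is.null(gait$hip_height)) {
    rlang::abort(paste0(
      "hip_height is not set; supply it to gait_params() (or the gait block ",
      "of the model config) to evaluate the Froude speed limit"),
      class = "flapmode_config_error")
  }
  sqrt(gait$froude_max * gait$gravity * gait$hip_height)
}

#' Resonant running speed per mode
#'
#' Maps every natural frequency to the running speed at which footfall
#' forcing matches it, flags excitable and flapping modes, and marks speeds
#' within the Froude limit. The flapping window -- the speed range over
#' which excitable flapping modes resonate -- is attached as attribute
#' `"flapping_window"` (`c(NA, NA)` with a warning when no mode qualifies).
#'
#' @param result A `modal_result` from [solve_modes()].
#' @param gait A [gait_params()].
#' @param eff_mass_threshold Passed to [classify_modes()].
#' @return A tibble: `mode`, `freq_hz`, `v_resonant`, `effective_mass`,
#'   `symmetry`, `excitable`, `flapping`, `within_froude_limit` (NA when
#'   `hip_height` is unset).
#' @export
#' @examples
#' resonance_speed_table(solve_modes(caudipteryx_model()), caudipteryx_gait())
resonance_speed_table <- function(result, gait, eff_mass_threshold = NULL) {
  cls <- classify_modes(result, eff_mass_threshold)
  v <- speed_from_frequency(cls$freq_hz, gait)
  vmax <- if (is.null(gait$hip_height)) NA_real_ else froude_max_speed(gait)
  out <- dplyr::mutate(
    dplyr::select(cls, "mode", "freq_hz", "effective_mass", "symmetry",
      "excitable", "flapping"),
    v_resonant = v,
    within_froude_limit = if (is.na(vmax)) NA else v <= vmax,
    .after = "freq_hz"
  )
  flap_v <- v[cls$flapping]
  if (length(flap_v) == 0) {
    rlang::warn("no excitable flapping mode: flapping window is empty")
    window <- c(NA_real_, NA_real_)
  } else {
    window <- range(flap_v)
  }
  attr(out, "flapping_window") <- window
  attr(out, "froude_max_speed") <- vmax
  out
}
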