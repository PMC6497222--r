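#' Plot a modal result
#'
#' Bar chart of effective-mass fraction per mode, annotated with frequency
#' and colored by excitability; flapping modes are outlined.
#'
#' @param object A `modal_result`.
#' @param ... Passed to [classify_modes()].
#' @return A ggplot.
#' @method autoplot modal_result
#' @export
autoplot.modal_result <- function(object, ...) {
  cls <- classify_modes(object, ...)
  ggplot2::ggplot(cls, ggplot2::aes(
    x = factor(.data$mode), y = .data$eff_mass_fraction,
    fill = .data$excitable)) +
    ggplot2::geom_col(ggplot2::aes(linewidth = .data$flapping),
      color = "black") +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1, `FALSE` = 0.2),
      guide = "none") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f Hz", .data$freq_hz)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "mode", y = "effective-mass fraction",
      title = "Modal effective mass",
      subtitle = "outlined = flapping mode") +
    ggplot2::theme_minimal()
}

#' Plot a frequency-response function
#'
#' @param object A `flapmode_frf` tibble from [frf_base_excitation()].
#' @param dofs Optional subset of DOF labels to draw.
#' @param ... Unused.
#' @return A ggplot (log-scale amplitude per DOF over frequency).
#' @method autoplot flapmode_frf
#' @export
autoplot.flapmode_frf <- function(object, dofs = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"freq_hz",
    names_to = "dof", values_to = "amplitude")
  if (!is.null(dofs)) long <- dplyr::filter(long, .data$dof %in% dofs)
  ggplot2::ggplot(long, ggplot2::aes(.data$freq_hz, .data$amplitude,
    color = .data$dof)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "drive frequency (Hz)", y = "amplitude (m)",
      title = "Base-excitation frequency response") +
    ggplot2::theme_minimal()
}

#' Plot a simulated time response
#'
#' @param object A `flapmode_response` tibble.
#' @param dofs Optional subset of DOF labels.
#' @param ... Unused.
#' @return A ggplot of displacement time series.
#' @method autoplot flapmode_response
#' @export
autoplot.flapmode_response <- function(object, dofs = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
    names_to = "dof", values_to = "displacement")
  if (!is.null(dofs)) long <- dplyr::filter(long, .data$dof %in% dofs)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$displacement,
    color = .data$dof)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "displacement (m)",
      title = "Footfall-forced response") +
    ggplot2::theme_minimal()
}

#' Plot a mass-scaling study
#'
#' @param object A `scaling_study` tibble.
#' @param ... Unused.
#' @return A ggplot of flapping-resonance speed against total mass.
#' @method autoplot scaling_study
#' @export
autoplot.scaling_study <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
    ggplot2::aes(.data$total_mass, .data$flap_speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "total mass (kg)", y = "flapping resonance speed (m/s)",
      title = "Heavier bipeds reach flapping resonance at lower speed") +
    ggplot2::theme_minimal()
}

#' Plot interval bounds on modal frequencies
#'
#' @param object An `interval_result` tibble.
#' @param ... Unused.
#' @return A ggplot with one frequency interval per mode.
#' @method autoplot interval_result
#' @export
autoplot.interval_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
    ggplot2::aes(x = factor(.data$mode))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$f_lo, ymax = .data$f_hi),
      width = 0.3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f_nominal), color = "red") +
    ggplot2::labs(x = "mode", y = "frequency (Hz)",
      title = "Interval bounds on natural frequencies",
      subtitle = "red = nominal model") +
    ggplot2::theme_minimal()
}
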