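#' Damping specification
#'
#' Small damping barely shifts natural frequencies (under 10% modal damping
#' the shift is below half a percent) but it caps resonant amplitudes, so
#' forced-response computations require it. Two forms are supported:
#' `"modal"` assigns a damping ratio per mode (a physical damping matrix is
#' reconstructed through the mode shapes), `"rayleigh"` builds
#' `C = alpha M + beta K`, whose implied modal ratio is
#' `zeta_i = alpha / (2 omega_i) + beta omega_i / 2`.
#'
#' @param kind `"modal"` or `"rayleigh"`.
#' @param ratio Modal damping ratio(s) in `[0, 1)`, recycled across modes.
#'   Default 0.05, a conservative soft-tissue value.
#' @param alpha Rayleigh mass coefficient, 1/s.
#' @param beta Rayleigh stiffness coefficient, s.
#' @return An object of class `damping_spec`.
#' @export
damping_spec <- function(kind = c("modal", "rayleigh"), ratio = 0.05,
                         alpha = 0, beta = 0) {
  kind <- match.arg(kind)
  if (kind == "modal" && any(ratio < 0 | ratio >= 1)) {
    rlang::abort("modal damping ratios must lie in [0, 1)",
      class = "flapmode_validation_error")
  }
  if (kind == "rayleigh" && (alpha < 0 || beta < 0)) {
    rlang::abort("Rayleigh coefficients must be >= 0",
      class = "flapmode_validation_error")
  }
  structure(list(kind = kind, ratio = ratio, alpha = alpha, beta = beta),
    class = "damping_spec")
}

# Per-mode damping ratios implied by a spec for a given modal solution.
modal_ratios <- function(damping, omega) {
  if (damping$kind == "modal") {
    rep_len(damping$ratio, length(omega))
  } else {
    zeta <- ifelse(omega > 0,
      damping$alpha / (2 * omega) + damping$beta * omega / 2, 0)
    zeta
  }
}

#' Physical damping matrix for a model
#'
#' @param model A [lumped_model()].
#' @param damping A [damping_spec()].
#' @param result Optional pre-computed [solve_modes()] result (modal kind).
#' @return An `n x n` damping matrix in N s/m.
#' @export
damping_matrix <- function(model, damping, result = NULL) {
  if (damping$kind == "rayleigh") {
    return(damping$alpha * model$mass_matrix + damping$beta * model$stiffness_matrix)
  }
  if (is.null(result)) result <- solve_modes(model)
  zeta <- rep_len(damping$ratio, length(result$omega))
  M <- model$mass_matrix
  MPhi <- M %*% result$mode_shapes
  MPhi %*% (diag(2 * zeta * result$omega, length(zeta)) %*% t(MPhi))
}

#' Footfall base excitation
#'
#' Running feet prescribe a vertical ground displacement under the foot
#' springs, which enters the equations of motion as a force
#' `k_ground * u(t)` at each leg DOF. `phase_split` selects whether both
#' feet move together (`"in_phase"`, the uniform vertical base motion of
#' the effective-mass analysis) or alternate (`"alternating"`, left foot up
#' while right foot down).
#'
#' @param drive_frequency Hz.
#' @param base_amplitude Ground displacement amplitude in m, `>= 0`.
#' @param phase_split `"in_phase"` or `"alternating"`.
#' @return An object of class `harmonic_excitation`.
#' @export
harmonic_excitation <- function(drive_frequency, base_amplitude = 0.01,
                                phase_split = c("in_phase", "alternating")) {
  phase_split <- match.arg(phase_split)
  if (base_amplitude < 0) {
    rlang::abort("base_amplitude must be >= 0", class = "flapmode_validation_error")
  }
  if (drive_frequency < 0) {
    rlang::abort("drive_frequency must be >= 0", class = "flapmode_validation_error")
  }
  structure(list(drive_frequency = drive_frequency,
    base_amplitude = base_amplitude, phase_split = phase_split),
    class = "harmonic_excitation")
}

# Static force pattern (per unit ground displacement) of a phase split.
base_force_pattern <- function(model, phase_split) {
  f0 <- numeric(model$n_dof)
  legs <- names(model$ground_stiffness)
  if (length(legs) == 0) {
    rlang::abort("model has no ground springs: base excitation has no entry point",
      class = "flapmode_config_error")
  }
  sgn <- rep(1, length(legs))
  if (phase_split == "alternating") {
    side <- model$segments$side[match(legs, model$segments$label)]
    sgn <- ifelse(side == "right", -1, 1)
  }
  idx <- match(legs, model$dof_labels)
  f0[idx] <- sgn * model$ground_stiffness
  f0
}

#' Frequency-response function under footfall base excitation
#'
#' Steady-state displacement amplitude of every DOF across a grid of drive
#' frequencies, from the complex solve
#' `(K - w^2 M + i w C) X = F0` with `F0 = k_ground * amplitude` at the leg
#' DOFs. Peaks appear only at modes the excitation pattern can reach: modes
#' with zero effective mass (for in-phase forcing) produce no peak.
#' Requires strictly positive damping in every mode, otherwise the response
#' at resonance is unbounded.
#'
#' @param model A [lumped_model()] with ground springs.
#' @param damping A [damping_spec()] with all modal ratios > 0.
#' @param excitation A [harmonic_excitation()] (its `drive_frequency` is
#'   ignored; the grid is swept instead).
#' @param freq_grid Frequencies to evaluate, Hz.
#' @return A tibble of class `flapmode_frf`: `freq_hz` plus one amplitude
#'   column (m) per DOF label.
#' @export
#' @examples
#' frf <- frf_base_excitation(caudipteryx_model(), damping_spec(ratio = 0.05),
#'   harmonic_excitation(2, 0.01), freq_grid = seq(0.5, 16, by = 0.05))
frf_base_excitation <- function(model, damping, excitation, freq_grid) {
  stopifnot(inherits(model, "lumped_model"), inherits(damping, "damping_spec"),
    inherits(excitation, "harmonic_excitation"))
  res <- solve_modes(model)
  zeta <- modal_ratios(damping, res$omega)
  if (any(zeta <= 0)) {
    rlang::abort(paste0(
      "all modal damping ratios must be > 0 for a bounded steady-state ",
      "response (undamped resonance is singular)"),
      class = "flapmode_validation_error")
  }
  C <- damping_matrix(model, damping, result = res)
  f0 <- base_force_pattern(model, excitation$phase_split) *
    excitation$base_amplitude
  M <- model$mass_matrix; K <- model$stiffness_matrix
  amp <- vapply(freq_grid, function(f) {
    w <- 2 * pi * f
    Mod(solve(K - w^2 * M + 1i * w * C, f0))
  }, numeric(model$n_dof))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(t(amp)), model$dof_labels))
  out <- dplyr::bind_cols(tibble::tibble(freq_hz = freq_grid), out)
  class(out) <- c("flapmode_frf", class(out))
  attr(out, "phase_split") <- excitation$phase_split
  attr(out, "base_amplitude") <- excitation$base_amplitude
  out
}

# Newmark average-acceleration integration of M a + C v + K x = F(t).
# Unconditionally stable; F is an n x (n_steps + 1) matrix of force samples.
newmark_integrate <- function(M, C, K, F, dt, x0, v0) {
  beta <- 0.25; gamma <- 0.5
  n_steps <- ncol(F) - 1L
  n <- nrow(M)
  a0 <- solve(M, F[, 1] - C %*% v0 - K %*% x0)
  Keff <- K + (gamma / (beta * dt)) * C + (1 / (beta * dt^2)) * M
  R <- chol(Keff)
  X <- matrix(0, n, n_steps + 1L)
  V <- matrix(0, n, n_steps + 1L)
  X[, 1] <- x0; V[, 1] <- v0
  x <- x0; v <- drop(v0); a <- drop(a0)
  c1 <- 1 / (beta * dt^2); c2 <- 1 / (beta * dt); c3 <- 1 / (2 * beta) - 1
  c4 <- gamma / (beta * dt); c5 <- gamma / beta - 1
  c6 <- dt * (gamma / (2 * beta) - 1)
  for (s in seq_len(n_steps)) {
    rhs <- F[, s + 1] +
      M %*% (c1 * x + c2 * v + c3 * a) +
      C %*% (c4 * x + c5 * v + c6 * a)
    xn <- backsolve(R, forwardsolve(t(R), rhs))
    an <- c1 * (xn - x) - c2 * v - c3 * a
    vn <- v + dt * ((1 - gamma) * a + gamma * an)
    x <- drop(xn); v <- drop(vn); a <- drop(an)
    X[, s + 1] <- x; V[, s + 1] <- v
  }
  list(X = X, V = V)
}

# Ground displacement waveform sampled on t; period = 1/freq.
footfall_waveform <- function(t, freq, amplitude,
                              waveform = c("sinusoid", "raised_cosine"),
                              duty = 0.4) {
  waveform <- match.arg(waveform)
  if (waveform == "sinusoid") {
    amplitude * sin(2 * pi * freq * t)
  } else {
    tau <- (t * freq) %% 1
    ifelse(tau < duty,
      amplitude * 0.5 * (1 - cos(2 * pi * tau / duty)), 0)
  }
}

#' Simulate the damped response to running at a given speed
#'
#' Integrates the damped equations of motion under periodic footfall base
#' displacement at the cycle frequency implied by the running speed, using
#' the implicit Newmark average-acceleration scheme (unconditionally
#' stable). The first half of the record is treated as transient and
#' discarded when summarizing; the steady-state wing oscillation amplitude
#' is attached as attribute `"wing_amplitude"`.
#'
#' @param model A [lumped_model()] with ground springs.
#' @param damping A [damping_spec()].
#' @param gait A [gait_params()].
#' @param speed Running speed, m/s, > 0.
#' @param duration Record length in s; must cover at least 20 forcing
#'   cycles.
#' @param base_amplitude Ground displacement amplitude, m.
#' @param waveform `"sinusoid"` (default) or `"raised_cosine"` pulse train
#'   (duty 0.4); the choice is recorded in the output metadata.
#' @param phase_split `"in_phase"` or `"alternating"`.
#' @param dt Time step, s; default 1/60 of the shortest period present.
#'   Steps coarser than 1/50 of the shortest period are refused.
#' @param seed Recorded in the metadata for provenance (the simulation
#'   itself is deterministic).
#' @return A tibble of class `flapmode_response`: `time` plus one
#'   displacement column (m) per DOF. Attributes: `wing_amplitude` (m, max
#'   over wing DOFs of the steady-state half-range), `metadata` list.
#' @export
simulate_running_response <- function(model, damping, gait, speed, duration,
                                      base_amplitude = 0.01,
                                      waveform = c("sinusoid", "raised_cosine"),
                                      phase_split = c("in_phase", "alternating"),
                                      dt = NULL, seed = 0L) {
  waveform <- match.arg(waveform)
  phase_split <- match.arg(phase_split)
  if (speed <= 0) {
    rlang::abort("speed must be > 0", class = "flapmode_validation_error")
  }
  drive_hz <- frequency_from_speed(speed, gait)
  if (duration * drive_hz < 20) {
    rlang::abort(sprintf(
      "duration %.3g s covers only %.1f forcing cycles; at least 20 required",
      duration, duration * drive_hz), class = "flapmode_validation_error")
  }
  res <- solve_modes(model)
  w_max <- max(res$omega, 2 * pi * drive_hz)
  T_min <- 2 * pi / w_max
  if (is.null(dt)) dt <- T_min / 60
  if (dt > T_min / 50) {
    rlang::abort(sprintf(
      "dt = %.3g s is coarser than 1/50 of the shortest period (%.3g s)",
      dt, T_min), class = "flapmode_validation_error")
  }
  C <- damping_matrix(model, damping, result = res)
  t <- seq(0, duration, by = dt)
  u <- footfall_waveform(t, drive_hz, base_amplitude, waveform)
  f0 <- base_force_pattern(model, phase_split)
  F <- outer(f0, u)
  sol <- newmark_integrate(model$mass_matrix, C, model$stiffness_matrix, F,
    dt, numeric(model$n_dof), numeric(model$n_dof))
  out <- dplyr::bind_cols(tibble::tibble(time = t),
    tibble::as_tibble(stats::setNames(as.data.frame(t(sol$X)),
      model$dof_labels)))
  class(out) <- c("flapmode_response", class(out))
  steady <- t >= duration / 2
  wings <- model$dof_labels[model$segments$role == "wing"]
  wing_amp <- if (length(wings) > 0) {
    max(vapply(wings, function(l) diff(range(out[[l]][steady])) / 2,
      numeric(1)))
  } else NA_real_
  attr(out, "wing_amplitude") <- wing_amp
  attr(out, "steady_amplitude") <- vapply(model$dof_labels,
    function(l) diff(range(out[[l]][steady])) / 2, numeric(1))
  attr(out, "metadata") <- list(speed = speed, drive_frequency_hz = drive_hz,
    waveform = waveform, phase_split = phase_split,
    base_amplitude = base_amplitude, dt = dt, seed = seed)
  out
}

#' Free decay from an initial state
#'
#' Integrates the damped homogeneous system from initial displacements and
#' velocities with no forcing, e.g. to inspect energy dissipation.
#'
#' @inheritParams simulate_running_response
#' @param x0,v0 Initial displacement (m) and velocity (m/s) vectors.
#' @return A `flapmode_response` tibble with an `energy` attribute:
#'   total mechanical energy `(v'Mv + x'Kx)/2` at each step.
#' @export
simulate_free_decay <- function(model, damping, x0, v0 = NULL, duration = 2,
                                dt = NULL) {
  res <- solve_modes(model)
  T_min <- 2 * pi / max(res$omega[res$omega > 0])
  if (is.null(dt)) dt <- T_min / 60
  if (is.null(v0)) v0 <- numeric(model$n_dof)
  C <- damping_matrix(model, damping, result = res)
  t <- seq(0, duration, by = dt)
  F <- matrix(0, model$n_dof, length(t))
  sol <- newmark_integrate(model$mass_matrix, C, model$stiffness_matrix, F,
    dt, x0, v0)
  M <- model$mass_matrix; K <- model$stiffness_matrix
  energy <- vapply(seq_along(t), function(s) {
    0.5 * drop(crossprod(sol$V[, s], M %*% sol$V[, s])) +
      0.5 * drop(crossprod(sol$X[, s], K %*% sol$X[, s]))
  }, numeric(1))
  out <- dplyr::bind_cols(tibble::tibble(time = t),
    tibble::as_tibble(stats::setNames(as.data.frame(t(sol$X)),
      model$dof_labels)))
  class(out) <- c("flapmode_response", class(out))
  attr(out, "energy") <- energy
  out
}

#' Damped natural-frequency shift
#'
#' For modal damping the damped frequency is
#' `omega_d = omega * sqrt(1 - zeta^2)`, so ratios at or below 10% shift
#' frequencies by less than half a percent -- the justification for
#' computing natural modes without damping.
#'
#' @param model A [lumped_model()].
#' @param damping A [damping_spec()] with all ratios < 1.
#' @return A tibble: `mode`, `zeta`, `omega_undamped`, `omega_damped`,
#'   `relative_shift`.
#' @export
damped_frequency_shift <- function(model, damping) {
  res <- solve_modes(model)
  zeta <- modal_ratios(damping, res$omega)
  if (any(zeta >= 1)) {
    rlang::abort("damped_frequency_shift requires underdamped modes (zeta < 1)",
      class = "flapmode_validation_error")
  }
  wd <- res$omega * sqrt(1 - zeta^2)
  tibble::tibble(
    mode = seq_along(res$omega),
    zeta = zeta,
    omega_undamped = res$omega,
    omega_damped = wd,
    relative_shift = ifelse(res$omega > 0, 1 - wd / res$omega, 0)
  )
}

#' Sum-of-sinusoids waveforms
#'
#' Container for waveforms of the form
#' `theta(t) = sum_j a_j * sin(w_j t + p_j)` used to describe measured
#' flapping-angle traces.
#'
#' @param amplitude Amplitudes (degrees).
#' @param angular_frequency Angular frequencies (rad/s, `>= 0`).
#' @param phase Phases (rad).
#' @return A tibble of class `sinusoid_sum`.
#' @export
sinusoid_sum <- function(amplitude = numeric(), angular_frequency = numeric(),
                         phase = numeric()) {
  if (any(!is.finite(c(amplitude, angular_frequency, phase)))) {
    rlang::abort("sinusoid terms must be finite", class = "flapmode_validation_error")
  }
  if (any(angular_frequency < 0)) {
    rlang::abort("angular frequencies must be >= 0",
      class = "flapmode_validation_error")
  }
  out <- tibble::tibble(amplitude = as.numeric(amplitude),
    angular_frequency = as.numeric(angular_frequency),
    phase = as.numeric(phase))
  class(out) <- c("sinusoid_sum", class(out))
  out
}

#' Evaluate a sum of sinusoids
#'
#' @param w A [sinusoid_sum()].
#' @param t Time grid, s.
#' @return Numeric vector, degrees; identically zero for an empty term list.
#' @export
eval_sinusoid_sum <- function(w, t) {
  stopifnot(inherits(w, "sinusoid_sum"))
  out <- numeric(length(t))
  for (j in seq_len(nrow(w))) {
    out <- out + w$amplitude[j] * sin(w$angular_frequency[j] * t + w$phase[j])
  }
  out
}

#' Fit a sum of sinusoids to a sampled waveform
#'
#' Least-squares fit of `n_terms` sinusoids by variable projection: the
#' frequencies are optimized numerically (Nelder-Mead from multiple starts
#' seeded by periodogram peaks plus random jitter) while, for any candidate
#' frequency set, amplitudes and phases are recovered exactly by linear
#' least squares on the sin/cos basis. Reports the root-mean-square
#' residual; if no start converges, the best candidate is returned with a
#' warning and `converged = FALSE`.
#'
#' @param t Sample times, s (need not be uniform for evaluation, but the
#'   periodogram initialization assumes approximately uniform spacing).
#' @param y Sampled values (degrees).
#' @param n_terms Number of sinusoids.
#' @param seed Integer seed for the random multi-start.
#' @param n_starts Number of random starts.
#' @return A [sinusoid_sum()] with attributes `residual_rms` and
#'   `converged`.
#' @export
fit_sinusoid_sum <- function(t, y, n_terms, seed = 0L, n_starts = 20L) {
  if (length(t) != length(y)) {
    rlang::abort("t and y must have equal length", class = "flapmode_validation_error")
  }
  n_par <- 3L * n_terms
  if (length(y) < 3L * n_par) {
    rlang::abort(sprintf(
      "need at least %d samples to fit %d sinusoid terms (3 per parameter)",
      3L * n_par, n_terms), class = "flapmode_validation_error")
  }

  design <- function(freqs) {
    do.call(cbind, lapply(freqs, function(w) cbind(sin(w * t), cos(w * t))))
  }
  rss_of <- function(freqs) {
    if (any(freqs <= 0)) return(Inf)
    B <- design(freqs)
    fit <- tryCatch(stats::lm.fit(B, y), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    sum(fit$residuals^2)
  }

  dt_med <- stats::median(diff(t))
  spec <- stats::spec.pgram(stats::ts(y, deltat = dt_med), plot = FALSE,
    detrend = TRUE, taper = 0)
  # local periodogram maxima, strongest first, so each candidate is a
  # distinct spectral peak rather than adjacent bins of the same one
  s <- spec$spec
  is_peak <- c(FALSE, s[2:(length(s) - 1)] > s[1:(length(s) - 2)] &
    s[2:(length(s) - 1)] >= s[3:length(s)], FALSE)
  peak_w <- 2 * pi * spec$freq[is_peak][order(s[is_peak], decreasing = TRUE)]
  if (length(peak_w) == 0) peak_w <- 2 * pi * spec$freq[which.max(s)]
  peak_w <- peak_w[peak_w > 0]

  best <- NULL; best_rss <- Inf
  local_seed(seed)
  for (s in seq_len(n_starts)) {
    w0 <- if (s == 1 && length(peak_w) >= n_terms) {
      peak_w[seq_len(n_terms)]
    } else {
      base <- sample(peak_w[seq_len(min(length(peak_w), 4L * n_terms))],
        n_terms, replace = TRUE)
      base * stats::runif(n_terms, 0.8, 1.25)
    }
    opt <- stats::optim(w0, rss_of, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12))
    if (opt$value < best_rss) {
      best_rss <- opt$value
      best <- opt
    }
  }
  converged <- !is.null(best) && is.finite(best_rss) &&
    best$convergence == 0
  if (!converged) {
    rlang::warn("sinusoid fit did not converge; returning best candidate")
  }
  freqs <- abs(best$par)
  B <- design(freqs)
  cf <- stats::lm.fit(B, y)$coefficients
  cf[is.na(cf)] <- 0
  c_sin <- cf[seq(1, length(cf), by = 2)]
  c_cos <- cf[seq(2, length(cf), by = 2)]
  out <- sinusoid_sum(
    amplitude = sqrt(c_sin^2 + c_cos^2),
    angular_frequency = freqs,
    phase = atan2(c_cos, c_sin)
  )
  attr(out, "residual_rms") <- sqrt(best_rss / length(y))
  attr(out, "converged") <- converged
  out
}
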