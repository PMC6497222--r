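#' The seven-DOF Caudipteryx fixture
#'
#' The canonical lumped model of a 5 kg *Caudipteryx*: a central body
#' (2.4 kg) carrying two wings (0.5 kg each), two legs (0.2 kg each), a
#' tail (0.5 kg) and the neck/head (0.7 kg), with joint stiffnesses
#' 200 N/m per wing, 650 N/m per leg, 800 N/m each for tail and neck, and
#' 1000 N/m foot-ground springs under each leg. The gait block carries a
#' 0.50 m step (1.0 m stride), a Froude ceiling of 17 and a 0.384 m hip
#' height, together bounding running speed near 8 m/s.
#'
#' @return `caudipteryx_segments()` and `caudipteryx_joints()` return the
#'   component tibbles, `caudipteryx_gait()` the [gait_params()], and
#'   `caudipteryx_model()` the assembled [lumped_model()].
#' @export
#' @examples
#' caudipteryx_model()$total_mass  # 5 kg
caudipteryx_segments <- function() {
  segment_set(
    label = c("body", "wing_left", "wing_right", "leg_left", "leg_right",
      "tail", "neck_head"),
    mass_kg = c(2.4, 0.5, 0.5, 0.2, 0.2, 0.5, 0.7),
    role = c("body", "wing", "wing", "leg", "leg", "tail", "neck"),
    side = c("center", "left", "right", "left", "right", "center", "center")
  )
}

#' @rdname caudipteryx_segments
#' @export
caudipteryx_joints <- function() {
  joint_set(
    from = c("wing_left", "wing_right", "leg_left", "leg_right", "tail",
      "neck_head", "leg_left", "leg_right"),
    to = c(rep("body", 6), "GROUND", "GROUND"),
    stiffness = c(200, 200, 650, 650, 800, 800, 1000, 1000)
  )
}

#' @rdname caudipteryx_segments
#' @export
caudipteryx_gait <- function() {
  gait_params(step_length = 0.5, froude_max = 17, hip_height = 0.384)
}

#' @rdname caudipteryx_segments
#' @export
caudipteryx_model <- function() {
  lumped_model(caudipteryx_segments(), caudipteryx_joints())
}

#' Mass-scaled variant of the Caudipteryx model
#'
#' Rescales every segment mass proportionally to a requested total.
#' With `keep = "stiffness"` the joint stiffnesses stay at the fixture
#' values, so every natural frequency scales as `1/sqrt(c)` with the mass
#' factor `c` -- heavier animals resonate, and therefore reach their
#' flapping mode, at lower frequency and lower speed. With
#' `keep = "geometry"` stiffnesses are scaled by the same factor,
#' preserving all frequencies.
#'
#' @param total_mass Target total mass, kg, > 0.
#' @param keep `"stiffness"` (default) or `"geometry"`.
#' @return A [lumped_model()].
#' @export
#' @examples
#' m10 <- generate_scaled_model(10)
#' solve_modes(m10)$freq_hz[1]  # lowest mode drops with mass
generate_scaled_model <- function(total_mass, keep = c("stiffness", "geometry")) {
  keep <- match.arg(keep)
  if (!is.finite(total_mass) || total_mass <= 0) {
    rlang::abort("total_mass must be finite and > 0",
      class = "flapmode_validation_error")
  }
  seg <- caudipteryx_segments()
  jnt <- caudipteryx_joints()
  c_fac <- total_mass / sum(seg$mass_kg)
  seg$mass_kg <- seg$mass_kg * c_fac
  attr(seg, "total_mass") <- sum(seg$mass_kg)
  if (keep == "geometry") jnt$stiffness <- jnt$stiffness * c_fac
  lumped_model(seg, jnt)
}

#' Random symmetric star-topology model
#'
#' Draws a reproducible random biped: a central body plus `n_appendage_pairs`
#' left/right pairs (the first pair are grounded legs, further pairs wings),
#' optionally a tail and neck. Left and right members share mass and
#' stiffness, so the model is mirror-symmetric. Stiffnesses are drawn
#' log-uniformly over the requested range to cover decades evenly; masses
#' uniformly.
#'
#' @param n_appendage_pairs Number of left/right pairs, >= 1.
#' @param mass_range Length-2 positive range for segment masses, kg.
#' @param stiffness_range Length-2 positive range for stiffnesses, N/m.
#' @param seed Integer seed; the same seed gives an identical model.
#' @param extras Add an (unpaired) tail and neck segment.
#' @return A [lumped_model()].
#' @export
generate_random_model <- function(n_appendage_pairs = 2,
                                  mass_range = c(0.1, 5),
                                  stiffness_range = c(50, 5000),
                                  seed = 0L, extras = TRUE) {
  stopifnot(n_appendage_pairs >= 1, all(mass_range > 0),
    all(stiffness_range > 0))
  local_seed(seed)
  runif_log <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  labels <- "body"; masses <- stats::runif(1, mass_range[1], mass_range[2])
  roles <- "body"; sides <- "center"
  from <- character(0); to <- character(0); k <- numeric(0)
  for (p in seq_len(n_appendage_pairs)) {
    role <- if (p == 1) "leg" else "wing"
    m <- stats::runif(1, mass_range[1], mass_range[2])
    kj <- runif_log(1, stiffness_range)
    for (s in c("left", "right")) {
      lab <- paste0(role, p, "_", s)
      labels <- c(labels, lab); masses <- c(masses, m)
      roles <- c(roles, role); sides <- c(sides, s)
      from <- c(from, lab); to <- c(to, "body"); k <- c(k, kj)
    }
    if (p == 1) {
      kg <- runif_log(1, stiffness_range)
      for (s in c("left", "right")) {
        from <- c(from, paste0(role, p, "_", s)); to <- c(to, "GROUND")
        k <- c(k, kg)
      }
    }
  }
  if (extras) {
    for (lab in c("tail", "neck")) {
      labels <- c(labels, lab)
      masses <- c(masses, stats::runif(1, mass_range[1], mass_range[2]))
      roles <- c(roles, lab); sides <- c(sides, "center")
      from <- c(from, lab); to <- c(to, "body")
      k <- c(k, runif_log(1, stiffness_range))
    }
  }
  lumped_model(
    segment_set(labels, masses, roles, sides),
    joint_set(from, to, k)
  )
}

#' Mass-scaling study of the flapping resonance
#'
#' Runs the full pipeline over a family of proportionally mass-scaled
#' models and tabulates, per total mass, the flapping-mode frequency and
#' the running speed that excites it. Because stiffness is held fixed,
#' both decrease as `1/sqrt(mass)`: heavier animals need less speed to
#' reach their flapping resonance.
#'
#' @param mass_grid Ascending total masses, kg.
#' @param gait A [gait_params()]; default [caudipteryx_gait()].
#' @return A tibble of class `scaling_study`: `label`, `total_mass`,
#'   `flap_mode_freq` (Hz), `flap_speed` (m/s).
#' @export
#' @examples
#' scaling_study(seq(2, 10))
scaling_study <- function(mass_grid, gait = caudipteryx_gait()) {
  if (is.unsorted(mass_grid, strictly = TRUE)) {
    rlang::abort("mass_grid must be strictly ascending",
      class = "flapmode_validation_error")
  }
  rows <- purrr::map_dfr(seq_along(mass_grid), function(i) {
    m <- mass_grid[i]
    res <- solve_modes(generate_scaled_model(m))
    cls <- classify_modes(res)
    flap <- cls[cls$flapping, , drop = FALSE]
    f <- if (nrow(flap) > 0) {
      flap$freq_hz[which.max(flap$effective_mass)]
    } else NA_real_
    tibble::tibble(
      label = if (i <= 26L) LETTERS[i] else paste0("M", i),
      total_mass = m,
      flap_mode_freq = f,
      flap_speed = if (is.na(f)) NA_real_ else speed_from_frequency(f, gait)
    )
  })
  class(rows) <- c("scaling_study", class(rows))
  rows
}
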