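test_that("SDOF resonant amplification matches the closed form 1/(2 zeta)", {
  # one mass on a ground spring, driven through that spring
  seg <- segment_set(c("body", "leg"), c(1e-9, 1), c("body", "leg"))
  jnt <- joint_set(c("leg", "leg"), c("body", "GROUND"), c(0, 4))
  model <- lumped_model(seg, jnt)
  zeta <- 0.05
  fn <- 2 / (2 * pi)  # omega = 2 rad/s
  frf <- frf_base_excitation(model, damping_spec(ratio = zeta),
    harmonic_excitation(fn, base_amplitude = 0.01),
    freq_grid = fn * seq(0.9, 1.1, length.out = 201))
  peak <- max(frf$leg)
  expect_equal(peak / 0.01, 1 / (2 * zeta), tolerance = 0.01)
  # and the full curve matches the textbook transmissibility of the force
  w_grid <- 2 * pi * frf$freq_hz
  expect_equal(frf$leg,
    oracle_sdof_amplitude(1, 4, zeta, 4 * 0.01, w_grid), tolerance = 1e-6)
})

test_that("in-phase FRF peaks only at modes with effective mass", {
  model <- caudipteryx_model()
  res <- solve_modes(model)
  grid <- seq(0.5, 16, by = 0.01)
  frf <- frf_base_excitation(model, damping_spec(ratio = 0.02),
    harmonic_excitation(2, 0.01), freq_grid = grid)
  wing <- frf$wing_left
  # local maxima of the wing spectrum
  pk <- which(diff(sign(diff(wing))) == -2) + 1
  peak_f <- grid[pk]
  inert_f <- res$freq_hz[res$effective_mass < 1e-8]   # 20 and 90.8 rad/s modes
  live_f <- res$freq_hz[res$effective_mass >= 1e-8]
  for (f0 in peak_f) {
    # each peak is closer to an excitable mode than to any inert one
    expect_lt(min(abs(f0 - live_f)), min(abs(f0 - inert_f)))
  }
  # every strongly excitable mode inside the grid produces a peak
  for (f0 in live_f[live_f < max(grid)]) {
    expect_lt(min(abs(peak_f - f0)), 0.05)
  }
})

test_that("alternating footfalls excite the antisymmetric leg mode instead", {
  model <- caudipteryx_model()
  res <- solve_modes(model)
  cls <- classify_modes(res)
  f_leg_anti <- res$freq_hz[cls$symmetry == "antisymmetric" &
    abs(res$mode_shapes[4, ]) > 0.5]     # 90.8 rad/s leg mode
  grid <- seq(10, 16, by = 0.005)
  frf <- frf_base_excitation(model, damping_spec(ratio = 0.02),
    harmonic_excitation(2, 0.01, phase_split = "alternating"),
    freq_grid = grid)
  pk <- grid[which.max(frf$leg_left)]
  expect_equal(pk, f_leg_anti[1], tolerance = 0.01)
  # in-phase excitation instead peaks at the nearby symmetric leg mode
  f_leg_sym <- res$freq_hz[cls$symmetry == "symmetric" &
    abs(res$mode_shapes[4, ]) > 0.5]
  frf_sym <- frf_base_excitation(model, damping_spec(ratio = 0.02),
    harmonic_excitation(2, 0.01, phase_split = "in_phase"),
    freq_grid = grid)
  pk_sym <- grid[which.max(frf_sym$leg_left)]
  expect_equal(pk_sym, f_leg_sym[1], tolerance = 0.01)
  expect_gt(abs(pk_sym - pk), 0.1)
  # and the wings stay quiet under purely antisymmetric leg forcing
  expect_lt(max(frf$wing_left), 1e-3 * max(frf$leg_left))
})

test_that("zero damping is rejected for steady-state response", {
  expect_error(
    frf_base_excitation(caudipteryx_model(), damping_spec(ratio = 0),
      harmonic_excitation(2, 0.01), freq_grid = c(1, 2)),
    class = "flapmode_validation_error")
})

test_that("time integration reaches the FRF steady state", {
  model <- caudipteryx_model()
  damping <- damping_spec(ratio = 0.1)
  gait <- caudipteryx_gait()
  speed <- 3.0   # 3 Hz drive, off-resonance
  sim <- simulate_running_response(model, damping, gait, speed,
    duration = 40 / 3, base_amplitude = 0.01)
  drive_hz <- attr(sim, "metadata")$drive_frequency_hz
  expect_equal(drive_hz, 3)
  frf <- frf_base_excitation(model, damping, harmonic_excitation(drive_hz, 0.01),
    freq_grid = drive_hz)
  amp <- attr(sim, "steady_amplitude")
  for (lab in model$dof_labels) {
    expect_equal(unname(amp[lab]), frf[[lab]][1], tolerance = 0.02)
  }
})

test_that("resonant running beats off-resonant running on wing amplitude", {
  model <- caudipteryx_model()
  damping <- damping_spec(ratio = 0.05)
  gait <- caudipteryx_gait()
  res <- solve_modes(model)
  v_res <- speed_from_frequency(res$freq_hz[1], gait)
  on <- simulate_running_response(model, damping, gait, v_res, duration = 15)
  off <- simulate_running_response(model, damping, gait, 1.3 * v_res,
    duration = 15)
  expect_gt(attr(on, "wing_amplitude"), attr(off, "wing_amplitude"))
})

test_that("zero base amplitude gives identically zero response", {
  sim <- simulate_running_response(caudipteryx_model(), damping_spec(),
    caudipteryx_gait(), speed = 2, duration = 12, base_amplitude = 0)
  expect_equal(max(abs(as.matrix(sim[, -1]))), 0)
})

test_that("response is linear: superposition of forcing amplitudes", {
  model <- caudipteryx_model()
  args <- list(model = model, damping = damping_spec(ratio = 0.05),
    gait = caudipteryx_gait(), speed = 2.5, duration = 10)
  s1 <- do.call(simulate_running_response, c(args, base_amplitude = 0.003))
  s2 <- do.call(simulate_running_response, c(args, base_amplitude = 0.007))
  s3 <- do.call(simulate_running_response, c(args, base_amplitude = 0.010))
  add <- as.matrix(s1[, -1]) + as.matrix(s2[, -1])
  expect_equal(add, as.matrix(s3[, -1]), tolerance = 1e-8)
})

test_that("integration guardrails refuse coarse steps and short records", {
  model <- caudipteryx_model()
  expect_error(
    simulate_running_response(model, damping_spec(), caudipteryx_gait(),
      speed = 2, duration = 12, dt = 0.05),
    class = "flapmode_validation_error")
  expect_error(
    simulate_running_response(model, damping_spec(), caudipteryx_gait(),
      speed = 2, duration = 3),
    class = "flapmode_validation_error")
})

test_that("free decay dissipates mechanical energy monotonically", {
  model <- caudipteryx_model()
  res <- solve_modes(model)
  x0 <- res$mode_shapes[, 1] * 0.01 + res$mode_shapes[, 3] * 0.005
  sim <- simulate_free_decay(model, damping_spec(ratio = 0.05), x0,
    duration = 1.5)
  energy <- attr(sim, "energy")
  expect_true(all(diff(energy) <= 1e-10 * energy[1]))
  expect_lt(energy[length(energy)], energy[1])
})

test_that("damped frequency shift follows omega sqrt(1 - zeta^2)", {
  model <- caudipteryx_model()
  tab <- damped_frequency_shift(model, damping_spec(ratio = 0.1))
  expect_equal(tab$relative_shift, rep(1 - sqrt(0.99), 7), tolerance = 1e-12)
  expect_equal(tab$relative_shift[1], 0.005, tolerance = 0.01)
  tab0 <- damped_frequency_shift(model, damping_spec(ratio = 0))
  expect_equal(tab0$relative_shift, rep(0, 7))
  tab5 <- damped_frequency_shift(model, damping_spec(ratio = 0.05))
  expect_true(all(tab5$relative_shift < 0.0013))
})

test_that("FRF peak frequencies drift under 1% for zeta <= 0.1", {
  model <- caudipteryx_model()
  res <- solve_modes(model)
  f1 <- res$freq_hz[1]
  grid <- seq(0.97 * f1, 1.03 * f1, length.out = 601)
  for (z in c(0.02, 0.05, 0.1)) {
    frf <- frf_base_excitation(model, damping_spec(ratio = z),
      harmonic_excitation(2, 0.01), freq_grid = grid)
    f_pk <- grid[which.max(frf$wing_left)]
    expect_lt(abs(f_pk - f1) / f1, 0.01)
  }
})

test_that("sum-of-sinusoids evaluation is the literal term sum", {
  w <- sinusoid_sum(
    amplitude = c(932.7, 28.18, 898.2),
    angular_frequency = c(19.01, 15.25, 19.16),
    phase = c(-3.35, -5.103, 6.034))
  expect_equal(eval_sinusoid_sum(w, 0),
    932.7 * sin(-3.35) + 28.18 * sin(-5.103) + 898.2 * sin(6.034))
  t <- seq(0, 2, by = 0.01)
  manual <- 932.7 * sin(19.01 * t - 3.35) + 28.18 * sin(15.25 * t - 5.103) +
    898.2 * sin(19.16 * t + 6.034)
  expect_equal(eval_sinusoid_sum(w, t), manual)
  expect_equal(eval_sinusoid_sum(sinusoid_sum(), t), rep(0, length(t)))
})

test_that("sinusoid fit recovers a noisy 3-term synthetic signal", {
  truth <- sinusoid_sum(
    amplitude = c(20, 8, 3),
    angular_frequency = c(6.0, 14.5, 25.0),
    phase = c(0.4, -1.1, 2.0))
  t <- seq(0, 10, by = 0.01)
  withr::local_seed(7)
  y <- eval_sinusoid_sum(truth, t) + rnorm(length(t), sd = 0.01 * 20)
  fit <- fit_sinusoid_sum(t, y, n_terms = 3, seed = 1)
  ord <- order(fit$angular_frequency)
  expect_equal(fit$angular_frequency[ord], truth$angular_frequency,
    tolerance = 0.01)
  expect_equal(fit$amplitude[ord], truth$amplitude, tolerance = 0.05)
  expect_lt(attr(fit, "residual_rms"), 0.5)
  expect_error(fit_sinusoid_sum(t[1:20], y[1:20], n_terms = 3),
    class = "flapmode_validation_error")
})
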