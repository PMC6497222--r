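test_that("a width-zero box collapses every interval to the nominal point", {
  model <- caudipteryx_model()
  box <- interval_box(mass_scale = c(1, 1), `stiffness:wing_left:body` = c(200, 200))
  ib <- interval_modal_bounds(model, box, n_samples = 50, seed = 1)
  expect_equal(ib$f_lo, ib$f_nominal, tolerance = 1e-12)
  expect_equal(ib$f_hi, ib$f_nominal, tolerance = 1e-12)
})

test_that("mass-scaling box endpoints follow the closed-form 1/sqrt(c) law", {
  model <- caudipteryx_model()
  box <- interval_box(mass_scale = c(3, 7) / 5, step_length = c(0.30, 0.70))
  ib <- interval_modal_bounds(model, box, method = "vertex", seed = 1)
  f_nom <- solve_modes(model)$freq_hz
  # heaviest corner gives the lower end, lightest the upper, exactly
  expect_equal(ib$f_lo, f_nom / sqrt(7 / 5), tolerance = 1e-10)
  expect_equal(ib$f_hi, f_nom / sqrt(3 / 5), tolerance = 1e-10)
  sb <- interval_speed_bounds(ib, box, gait = caudipteryx_gait())
  expect_true(all(sb$v_lo <= sb$v_nominal & sb$v_nominal <= sb$v_hi))
  window <- attr(sb, "flapping_window")
  v_nom_flap <- sb$v_nominal[attr(ib, "flapping_mode")]
  expect_true(window[1] <= v_nom_flap && v_nom_flap <= window[2])
  # lower end of the window = heaviest mass at the shortest stride
  expect_equal(window[1], f_nom[1] / sqrt(7 / 5) * 0.60, tolerance = 1e-10)
})

test_that("sampled inner intervals nest inside vertex outer intervals", {
  model <- caudipteryx_model()
  withr::local_seed(99)
  for (b in 1:20) {
    lo_m <- runif(1, 0.5, 0.9); hi_m <- lo_m + runif(1, 0.05, 0.6)
    lo_k <- runif(1, 120, 190); hi_k <- lo_k + runif(1, 10, 80)
    box <- interval_box(mass_scale = c(lo_m, hi_m),
      `stiffness:wing_left:body` = c(lo_k, hi_k))
    ib <- interval_modal_bounds(model, box, n_samples = 60, seed = b)
    expect_true(all(ib$f_lo <= ib$f_lo_inner + 1e-12))
    expect_true(all(ib$f_hi_inner <= ib$f_hi + 1e-12))
    expect_true(all(ib$f_lo <= ib$f_nominal & ib$f_nominal <= ib$f_hi))
  }
})

test_that("inclusion monotonicity: wider boxes give wider intervals", {
  model <- caudipteryx_model()
  inner <- interval_box(mass_scale = c(0.8, 1.2))
  outer <- interval_box(mass_scale = c(0.6, 1.4))
  ib_in <- interval_modal_bounds(model, inner, method = "vertex")
  ib_out <- interval_modal_bounds(model, outer, method = "vertex")
  expect_true(all(ib_out$f_lo <= ib_in$f_lo & ib_in$f_hi <= ib_out$f_hi))
})

test_that("speed intervals are the exact positive-interval product", {
  model <- caudipteryx_model()
  ib <- interval_modal_bounds(model, interval_box(mass_scale = c(0.9, 1.1)),
    method = "vertex")
  # widen stride: the speed interval can only grow
  g <- caudipteryx_gait()
  narrow <- interval_box(mass_scale = c(1, 1), step_length = c(0.45, 0.55))
  wide <- interval_box(mass_scale = c(1, 1), step_length = c(0.30, 0.70))
  sb_n <- interval_speed_bounds(ib, narrow, gait = g)
  sb_w <- interval_speed_bounds(ib, wide, gait = g)
  expect_true(all(sb_w$v_lo <= sb_n$v_lo & sb_n$v_hi <= sb_w$v_hi))
  # point stride scales the frequency interval exactly
  sb_p <- interval_speed_bounds(ib, NULL, gait = g)
  expect_equal(sb_p$v_lo, ib$f_lo * 1.0)
  expect_equal(sb_p$v_hi, ib$f_hi * 1.0)
  # hand-checked positive-interval product: f in [2,3] Hz, stride in [0.6,1.4]
  fake <- ib[1, ]
  fake$f_lo <- 2; fake$f_hi <- 3; fake$f_nominal <- 2.5
  class(fake) <- class(ib)
  attr(fake, "flapping_mode") <- NA_integer_
  sb <- interval_speed_bounds(fake,
    interval_box(step_length = c(0.3, 0.7)), gait = g)
  expect_equal(c(sb$v_lo, sb$v_hi), c(1.2, 4.2))
})

test_that("vertex enumeration is refused beyond 16 parameters", {
  model <- caudipteryx_model()
  big <- tibble::tibble(
    parameter = c("mass_scale", paste0("mass:x", 1:16)),
    low = rep(0.9, 17), high = rep(1.1, 17))
  class(big) <- c("interval_box", class(big))
  expect_error(
    interval_modal_bounds(model, big, method = "vertex"),
    class = "flapmode_validation_error")
})

test_that("interval boxes validate their bounds", {
  expect_error(interval_box(mass_scale = c(1.2, 0.8)),
    class = "flapmode_validation_error")
  expect_error(interval_box(mass_scale = c(-1, 2)),
    class = "flapmode_validation_error")
  expect_error(interval_box(c(1, 2)), class = "flapmode_config_error")
})
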