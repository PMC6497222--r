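test_that("fixture eigenvalues and frequencies match the known 7-DOF spectrum", {
  res <- solve_modes(caudipteryx_model())
  expect_equal(res$omega, c(12.1, 20, 23.05, 36.4, 47.6, 90.8, 92.2),
    tolerance = 5e-3)
  expect_equal(res$freq_hz[1], 1.924, tolerance = 1e-3)
  expect_false(is.unsorted(res$omega))
})

test_that("single mass on a ground spring gives omega = sqrt(k/m)", {
  seg <- segment_set(c("body", "leg"), c(1e-9, 1), c("body", "leg"))
  # effectively a single 1-kg mass on a 4 N/m ground spring
  jnt <- joint_set(c("leg", "leg"), c("body", "GROUND"), c(0, 4))
  res <- solve_modes(lumped_model(seg, jnt))
  expect_equal(max(res$omega), 2, tolerance = 1e-6)
})

test_that("eigenvalues agree with the characteristic-polynomial oracle (n <= 4)", {
  for (seed in 1:8) {
    withr::local_seed(seed)
    n <- sample(2:4, 1)
    m <- runif(n, 0.2, 3)
    # random symmetric PSD stiffness with positive diagonal dominance
    K <- matrix(0, n, n)
    for (i in 2:n) {
      k <- runif(1, 50, 2000)
      K[1, 1] <- K[1, 1] + k; K[i, i] <- k
      K[1, i] <- -k; K[i, 1] <- -k
    }
    K[1, 1] <- K[1, 1] + runif(1, 100, 1000)  # ground spring on dof 1
    # compare the solver on (M, K) directly via a model stub
    model <- caudipteryx_model()
    model$mass_matrix <- diag(m, n)
    model$stiffness_matrix <- K
    model$n_dof <- n
    model$dof_labels <- paste0("s", 1:n)
    model$symmetry_pairs <- list()
    model$segments <- segment_set(paste0("s", 1:n), m,
      c("body", rep("wing", n - 1)))
    res <- solve_modes(model)
    expect_equal(res$omega, oracle_char_poly_omega(diag(m, n), K),
      tolerance = 1e-8)
  }
})

test_that("mode shapes are mass-orthonormal and diagonalize K", {
  for (seed in 1:100) {
    m <- random_fixture_like(seed)
    res <- solve_modes(m)
    G <- t(res$mode_shapes) %*% m$mass_matrix %*% res$mode_shapes
    expect_equal(G, diag(nrow(G)), tolerance = 1e-8)
    KG <- t(res$mode_shapes) %*% m$stiffness_matrix %*% res$mode_shapes
    expect_equal(diag(KG), res$omega^2, tolerance = 1e-8)
    expect_equal(max(abs(KG - diag(diag(KG)))), 0,
      tolerance = 1e-6 * max(res$omega^2))
  }
})

test_that("fixture participation and effective masses match the known values", {
  res <- solve_modes(caudipteryx_model())
  expect_equal(abs(res$participation),
    c(2.158, 0, 0.40, 0.10, 0.19, 0, 0.36), tolerance = 0.02)
  expect_equal(sum(res$effective_mass), 5, tolerance = 1e-10)
})

test_that("completeness holds for arbitrary influence vectors", {
  for (seed in 1:20) {
    m <- random_fixture_like(seed)
    withr::local_seed(seed + 1000)
    r <- rnorm(m$n_dof)
    res <- participation_and_effective_mass(solve_modes(m), m, influence = r)
    target <- drop(t(r) %*% m$mass_matrix %*% r)
    expect_equal(sum(res$effective_mass), target, tolerance = 1e-10 * abs(target))
  }
  expect_error(
    participation_and_effective_mass(solve_modes(caudipteryx_model()),
      influence = c(1, 1)),
    class = "flapmode_validation_error")
})

test_that("antisymmetric modes of symmetric models carry zero effective mass", {
  for (seed in 1:100) {
    m <- random_fixture_like(seed)
    res <- solve_modes(m)
    cls <- classify_modes(res)
    expect_true(all(cls$symmetry %in% c("symmetric", "antisymmetric")))
    anti <- cls$symmetry == "antisymmetric"
    expect_true(any(anti))  # paired appendages always produce some
    expect_lt(max(res$effective_mass[anti]), 1e-10)
  }
})

test_that("mass scaling divides every frequency by sqrt(c)", {
  base <- solve_modes(caudipteryx_model())
  for (c_fac in c(0.25, 0.5, 2, 4, 10)) {
    seg <- caudipteryx_segments()
    seg$mass_kg <- seg$mass_kg * c_fac
    scaled <- solve_modes(lumped_model(seg, caudipteryx_joints()))
    expect_equal(scaled$omega, base$omega / sqrt(c_fac),
      tolerance = 1e-10)
  }
})

test_that("mode classification identifies the flapping mode of the fixture", {
  res <- solve_modes(caudipteryx_model())
  cls <- classify_modes(res)
  # mode 2 (20 rad/s): antisymmetric wing mode, inert
  expect_equal(cls$symmetry[2], "antisymmetric")
  expect_false(cls$excitable[2])
  expect_lt(cls$effective_mass[2], 1e-12)
  # mode 1: dominant, symmetric, wings beat harder than the body bobs
  expect_true(cls$excitable[1])
  expect_equal(cls$symmetry[1], "symmetric")
  phi1 <- res$mode_shapes[, 1]
  expect_gt(abs(phi1[2]), abs(phi1[1]))
  expect_true(cls$flapping[1])
  # threshold 0 renders every mode with nonzero m_eff excitable
  cls0 <- classify_modes(res, eff_mass_threshold = 0)
  expect_true(all(cls0$excitable[res$effective_mass > 0]))
})

test_that("tidy and glance summarize a modal result coherently", {
  res <- solve_modes(caudipteryx_model())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 7)
  gl <- glance(res)
  expect_equal(gl$sum_effective_mass, 5, tolerance = 1e-10)
  expect_lt(abs(gl$completeness_gap), 1e-10)
  expect_equal(gl$n_flapping, 1)
})

test_that("exactly degenerate symmetric pairs are still labeled cleanly", {
  # two identical wing pairs -> degenerate antisymmetric eigenvalues
  seg <- segment_set(
    c("body", "w1L", "w1R", "w2L", "w2R", "legL", "legR"),
    c(2, 0.5, 0.5, 0.5, 0.5, 0.3, 0.3),
    c("body", "wing", "wing", "wing", "wing", "leg", "leg"),
    c("center", "left", "right", "left", "right", "left", "right"))
  jnt <- joint_set(
    c("w1L", "w1R", "w2L", "w2R", "legL", "legR", "legL", "legR"),
    c(rep("body", 6), "GROUND", "GROUND"),
    c(200, 200, 200, 200, 500, 500, 900, 900))
  cls <- classify_modes(solve_modes(lumped_model(seg, jnt)))
  expect_true(all(cls$symmetry %in% c("symmetric", "antisymmetric")))
})
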