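#' Solve the undamped free-vibration eigenproblem
#'
#' Computes all natural frequencies and mass-normalized mode shapes of a
#' lumped model from `det(K - omega^2 M) = 0`. Because the mass matrix is
#' diagonal and positive definite, the generalized problem is whitened to the
#' symmetric ordinary problem `M^(-1/2) K M^(-1/2)` and solved with a
#' symmetric eigensolver, which guarantees a real spectrum. Rigid-body modes
#' (zero eigenvalues of an ungrounded model) are returned with `omega = 0`,
#' not dropped. Each mode shape is scaled so `phi' M phi = 1` and signed so
#' its largest-magnitude component is positive.
#'
#' Participation factors and effective masses for the default all-ones
#' influence vector (uniform vertical base motion) are filled in as well;
#' use [participation_and_effective_mass()] to recompute them for a custom
#' influence vector.
#'
#' @param model A validated [lumped_model()] with positive-definite mass.
#' @return An object of class `modal_result`: list with `omega` (rad/s,
#'   ascending), `freq_hz`, `mode_shapes` (n x n, column i = mode i),
#'   `generalized_mass` (all ones under mass normalization),
#'   `participation` (Gamma, signed), `effective_mass` (kg, `Gamma^2`),
#'   `influence_vector`, and the `model`.
#' @seealso [classify_modes()], [tidy.modal_result()], [resonance_speed_table()]
#' @export
#' @examples
#' modes <- solve_modes(caudipteryx_model())
#' round(modes$omega, 2)     # 12.09 20 23.06 36.41 47.56 90.83 92.21
#' sum(modes$effective_mass) # 5 kg: completeness
solve_modes <- function(model) {
  stopifnot(inherits(model, "lumped_model"))
  m <- diag(model$mass_matrix)
  if (any(m <= 0)) {
    rlang::abort("mass matrix must be positive definite",
      class = "flapmode_validation_error")
  }
  n <- model$n_dof
  w <- 1 / sqrt(m)
  A <- model$stiffness_matrix * tcrossprod(w)  # M^(-1/2) K M^(-1/2)
  A <- (A + t(A)) / 2
  es <- tryCatch(eigen(A, symmetric = TRUE),
    error = function(e) {
      rlang::abort(sprintf(
        "eigen solution failed (%s); stiffness scale %.3g, condition est. %.3g",
        conditionMessage(e), max(abs(A)), kappa(A)),
        class = "flapmode_numerical_error")
    })
  ord <- order(es$values)
  lambda <- es$values[ord]
  lambda[abs(lambda) < 1e-9 * max(abs(lambda), 1)] <- 0
  if (any(lambda < 0)) {
    rlang::abort("stiffness matrix is indefinite: negative eigenvalue found",
      class = "flapmode_numerical_error")
  }
  Phi <- es$vectors[, ord, drop = FALSE] * w  # rows scaled by 1/sqrt(m)
  for (i in seq_len(n)) {
    j <- which.max(abs(Phi[, i]))
    if (Phi[j, i] < 0) Phi[, i] <- -Phi[, i]
  }
  res <- structure(list(
    omega = sqrt(lambda),
    freq_hz = sqrt(lambda) / (2 * pi),
    mode_shapes = Phi,
    generalized_mass = rep(1, n),
    model = model
  ), class = "modal_result")
  participation_and_effective_mass(res, model)
}

#' Participation factors and modal effective masses
#'
#' Projects each mass-weighted mode shape onto an influence vector `r` (the
#' rigid-body displacement pattern of the base excitation; all-ones for
#' uniform vertical motion). With mass-normalized modes the generalized mass
#' is 1, so the participation factor is `Gamma_i = phi_i' M r` and the
#' effective mass `m_eff,i = Gamma_i^2`. The effective masses decompose the
#' base-mobilized mass: their sum equals `r' M r` (the total mass when `r`
#' is all ones), so modes with near-zero effective mass cannot be excited
#' through the base.
#'
#' @param result A `modal_result` from [solve_modes()].
#' @param model The model (defaults to the one stored in `result`).
#' @param influence Influence vector of length `n_dof`; default all ones.
#' @return The `modal_result` with `participation`, `effective_mass` and
#'   `influence_vector` set for the given influence vector.
#' @export
participation_and_effective_mass <- function(result, model = result$model,
                                             influence = NULL) {
  stopifnot(inherits(result, "modal_result"))
  n <- model$n_dof
  if (is.null(influence)) influence <- rep(1, n)
  if (length(influence) != n) {
    rlang::abort(sprintf(
      "influence vector has length %d but the model has %d DOFs",
      length(influence), n), class = "flapmode_validation_error")
  }
  L <- drop(crossprod(result$mode_shapes, model$mass_matrix %*% influence))
  result$participation <- L          # Gamma = L / m_hat, with m_hat = 1
  result$effective_mass <- L^2
  result$influence_vector <- influence
  result
}

#' @export
print.modal_result <- function(x, ...) {
  cat("<modal_result> ", length(x$omega), " modes\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

# Symmetry label of one mode against the model's left/right pairs.
# Near-degenerate clusters are rotated onto the symmetric/antisymmetric
# subspaces first (callers pass already-rotated shapes).
mode_symmetry <- function(phi, pairs, tol = 1e-6) {
  if (length(pairs) == 0) return("symmetric")
  scale <- max(abs(phi))
  labs <- vapply(pairs, function(p) {
    l <- phi[p[1]]; r <- phi[p[2]]
    if (abs(l) < tol * scale && abs(r) < tol * scale) return("either")
    if (abs(l - r) < tol * scale) return("symmetric")
    if (abs(l + r) < tol * scale) return("antisymmetric")
    "mixed"
  }, character(1))
  labs <- labs[labs != "either"]
  if (length(labs) == 0) return("symmetric")
  if (all(labs == "symmetric")) return("symmetric")
  if (all(labs == "antisymmetric")) return("antisymmetric")
  "mixed"
}

# Rotate columns of Phi within near-degenerate eigenvalue clusters so each
# column lies in the symmetric or antisymmetric subspace where possible.
disambiguate_degenerate <- function(omega, Phi, model, rel_tol = 1e-6) {
  n <- length(omega)
  if (length(model$symmetry_pairs) == 0 || n < 2) return(Phi)
  scale <- max(omega, 1)
  cl <- cumsum(c(1, diff(omega) > rel_tol * scale))
  A <- diag(n)  # antisymmetrizer: swap left/right, negate
  for (p in model$symmetry_pairs) {
    A[p[1], p[1]] <- 0; A[p[2], p[2]] <- 0
    A[p[1], p[2]] <- 1; A[p[2], p[1]] <- 1
  }
  Pa <- (diag(n) - A) / 2  # projector onto antisymmetric part
  for (g in unique(cl)) {
    cols <- which(cl == g)
    if (length(cols) < 2) next
    C <- Phi[, cols, drop = FALSE]
    sv <- svd(Pa %*% C)
    rot <- C %*% sv$v
    M <- model$mass_matrix
    for (j in seq_along(cols)) {
      gm <- drop(crossprod(rot[, j], M %*% rot[, j]))
      if (gm > 1e-12) rot[, j] <- rot[, j] / sqrt(gm)
      k <- which.max(abs(rot[, j]))
      if (rot[k, j] < 0) rot[, j] <- -rot[, j]
    }
    Phi[, cols] <- rot
  }
  Phi
}

#' Classify modes as excitable and by left/right symmetry
#'
#' Labels each mode: *excitable* when its effective mass exceeds a threshold
#' (default 5% of total mass, which separates base-excitable modes from
#' inert ones), and *symmetric* / *antisymmetric* / *mixed* from the signs
#' of each left/right appendage pair in the mode shape. A *flapping* mode is
#' an excitable mode whose wing pair moves in phase (symmetric) with wing
#' amplitude exceeding the body amplitude -- both wings beating up and down
#' together harder than the torso bobs.
#'
#' @param result A `modal_result` from [solve_modes()].
#' @param eff_mass_threshold Effective-mass threshold in kg; default
#'   `0.05 * total_mass`.
#' @return A tibble with one row per mode: `mode`, `omega`, `freq_hz`,
#'   `participation` (magnitude), `effective_mass`, `eff_mass_fraction`,
#'   `symmetry`, `excitable`, `flapping`.
#' @export
#' @examples
#' classify_modes(solve_modes(caudipteryx_model()))
classify_modes <- function(result, eff_mass_threshold = NULL) {
  stopifnot(inherits(result, "modal_result"))
  model <- result$model
  if (is.null(eff_mass_threshold)) eff_mass_threshold <- 0.05 * model$total_mass
  Phi <- disambiguate_degenerate(result$omega, result$mode_shapes, model)
  n <- length(result$omega)
  wing_idx <- which(model$segments$role == "wing")
  body_idx <- which(model$segments$role == "body")
  wing_pairs <- Filter(function(p) all(p %in% wing_idx), model$symmetry_pairs)

  sym <- character(n)
  flap <- logical(n)
  for (i in seq_len(n)) {
    phi <- Phi[, i]
    sym[i] <- mode_symmetry(phi, model$symmetry_pairs)
    wings_in_phase <- length(wing_pairs) > 0 &&
      all(vapply(wing_pairs, function(p)
        mode_symmetry(phi, list(p)) == "symmetric", logical(1)))
    flap[i] <- wings_in_phase && length(wing_idx) > 0 &&
      max(abs(phi[wing_idx])) > abs(phi[body_idx])
  }
  excitable <- result$effective_mass > eff_mass_threshold
  tibble::tibble(
    mode = seq_len(n),
    omega = result$omega,
    freq_hz = result$freq_hz,
    participation = abs(result$participation),
    effective_mass = result$effective_mass,
    eff_mass_fraction = result$effective_mass / sum(result$effective_mass),
    symmetry = sym,
    excitable = excitable,
    flapping = excitable & flap
  )
}

#' Tidy a modal result into a per-mode tibble
#'
#' @param x A `modal_result`.
#' @param ... Passed to [classify_modes()] (e.g. `eff_mass_threshold`).
#' @return The [classify_modes()] tibble.
#' @method tidy modal_result
#' @export
tidy.modal_result <- function(x, ...) classify_modes(x, ...)

#' One-row summary of a modal result
#'
#' @param x A `modal_result`.
#' @param ... Unused.
#' @return A one-row tibble: mode count, frequency range, total and summed
#'   effective mass, completeness gap `sum(m_eff) - r' M r`, excitable count.
#' @method glance modal_result
#' @export
glance.modal_result <- function(x, ...) {
  r <- x$influence_vector
  target <- drop(crossprod(r, x$model$mass_matrix %*% r))
  cls <- classify_modes(x)
  tibble::tibble(
    n_modes = length(x$omega),
    f_min_hz = min(x$freq_hz),
    f_max_hz = max(x$freq_hz),
    total_mass = x$model$total_mass,
    sum_effective_mass = sum(x$effective_mass),
    completeness_gap = sum(x$effective_mass) - target,
    n_excitable = sum(cls$excitable),
    n_flapping = sum(cls$flapping)
  )
}
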