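#' Define the body segments of a lumped biped model
#'
#' A lumped model divides the animal into point masses: one central body and
#' a set of appendages (wings, legs, tail, neck/head), each moving only
#' vertically. `segment_set()` builds the segment table that [lumped_model()]
#' consumes and checks its invariants.
#'
#' @param label Character vector of unique segment names.
#' @param mass_kg Numeric vector of segment masses in kilograms; all positive.
#' @param role Character vector: one segment must be `"body"`; appendages are
#'   `"wing"`, `"leg"`, `"tail"`, `"neck"` or any other descriptive role.
#'   Only `"leg"` segments may carry ground springs.
#' @param side `"left"`, `"right"` or `"center"`. Left/right segments sharing
#'   a role form the symmetry pairs used for mode classification.
#'
#' @return A tibble with columns `label`, `mass_kg`, `role`, `side` and
#'   attribute `total_mass`.
#' @seealso [joint_set()], [lumped_model()], [caudipteryx_segments()]
#' @export
#' @examples
#' segment_set(
#'   label = c("body", "wing_L", "wing_R"),
#'   mass_kg = c(2.4, 0.5, 0.5),
#'   role = c("body", "wing", "wing"),
#'   side = c("center", "left", "right")
#' )
segment_set <- function(label, mass_kg, role, side = NULL) {
  if (is.null(side)) side <- rep("center", length(label))
  seg <- tibble::tibble(
    label = as.character(label),
    mass_kg = as.numeric(mass_kg),
    role = as.character(role),
    side = as.character(side)
  )
  validate_segments(seg)
  attr(seg, "total_mass") <- sum(seg$mass_kg)
  seg
}

validate_segments <- function(seg) {
  required <- c("label", "mass_kg", "role", "side")
  missing <- setdiff(required, names(seg))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "segment table is missing column(s): ",
      paste(missing, collapse = ", ")
    ), class = "flapmode_config_error")
  }
  if (anyDuplicated(seg$label)) {
    rlang::abort("duplicate segment labels are not allowed",
      class = "flapmode_config_error")
  }
  if (any(!is.finite(seg$mass_kg)) || any(seg$mass_kg <= 0)) {
    rlang::abort("all segment masses must be finite and > 0",
      class = "flapmode_validation_error")
  }
  if (sum(seg$role == "body") != 1L) {
    rlang::abort("exactly one segment must have role 'body'",
      class = "flapmode_config_error")
  }
  bad_side <- setdiff(unique(seg$side), c("left", "right", "center"))
  if (length(bad_side) > 0) {
    rlang::abort(paste0("unknown side value(s): ", paste(bad_side, collapse = ", ")),
      class = "flapmode_config_error")
  }
  invisible(seg)
}

#' Define the spring joints of a lumped biped model
#'
#' Joints attach each appendage to the central body with a linear spring
#' (the lumped stand-in for joint musculature), and legs additionally to the
#' ground through foot springs. The topology is a star: appendages connect
#' only to the body, and `"GROUND"` only to legs.
#'
#' @param from Character vector of appendage labels.
#' @param to Character vector: the body label, or `"GROUND"` for foot springs.
#' @param stiffness Numeric spring constants in N/m, all `>= 0`.
#' @param damping_ratio Optional per-joint damping ratio in `[0, 1)`;
#'   recorded on the model and used as metadata (system-level damping is
#'   specified with [damping_spec()]).
#'
#' @return A tibble with columns `from`, `to`, `stiffness`, `damping_ratio`.
#' @export
joint_set <- function(from, to, stiffness, damping_ratio = 0) {
  jnt <- tibble::tibble(
    from = as.character(from),
    to = as.character(to),
    stiffness = as.numeric(stiffness),
    damping_ratio = rep_len(as.numeric(damping_ratio), length(from))
  )
  if (any(!is.finite(jnt$stiffness)) || any(jnt$stiffness < 0)) {
    rlang::abort("joint stiffnesses must be finite and >= 0",
      class = "flapmode_validation_error")
  }
  if (any(jnt$damping_ratio < 0 | jnt$damping_ratio >= 1)) {
    rlang::abort("joint damping ratios must lie in [0, 1)",
      class = "flapmode_validation_error")
  }
  jnt
}

#' Assemble a lumped mass-spring model of a running biped
#'
#' Builds the mass and stiffness matrices of a star-topology vertical-motion
#' model: every appendage mass couples to the central body through its joint
#' spring, and leg masses are additionally grounded through foot springs.
#' The stiffness pattern is the standard lumped assembly -- the body diagonal
#' carries the sum of all body-attached joint stiffnesses, each appendage
#' diagonal its own joint stiffness (plus the ground stiffness for a leg),
#' and each body--appendage off-diagonal the negated joint stiffness.
#'
#' @param segments A segment table from [segment_set()] (or an equivalent
#'   tibble with columns `label`, `mass_kg`, `role`, `side`).
#' @param joints A joint table from [joint_set()].
#'
#' @return An object of class `lumped_model`: a list with elements
#'   `n_dof`, `mass_matrix` (diagonal, kg), `stiffness_matrix` (N/m),
#'   `dof_labels`, `symmetry_pairs` (list of left/right index pairs),
#'   `ground_stiffness` (named, per leg DOF), `total_mass`, and the input
#'   `segments` and `joints` tables.
#' @seealso [validate_model()], [solve_modes()], [caudipteryx_model()]
#' @export
#' @examples
#' model <- caudipteryx_model()
#' model$stiffness_matrix[1, 1]  # 3300 N/m
lumped_model <- function(segments, joints) {
  validate_segments(segments)
  n <- nrow(segments)
  labels <- segments$label
  body <- labels[segments$role == "body"]

  known <- c(labels, "GROUND")
  bad <- setdiff(c(joints$from, joints$to), known)
  if (length(bad) > 0) {
    rlang::abort(paste0("joint endpoint(s) name unknown segments: ",
      paste(unique(bad), collapse = ", ")), class = "flapmode_config_error")
  }
  if (any(joints$from == "GROUND")) {
    rlang::abort("'GROUND' may only appear in the 'to' column",
      class = "flapmode_config_error")
  }

  is_ground <- joints$to == "GROUND"
  # star topology: every non-ground joint must attach an appendage to the body
  non_star <- !is_ground & joints$to != body
  if (any(non_star)) {
    rlang::abort(paste0(
      "non-star couplings are not supported (appendages attach only to the ",
      "body): ", paste(joints$from[non_star], "--", joints$to[non_star],
      collapse = ", ")), class = "flapmode_config_error")
  }
  if (any(joints$from[!is_ground] == body)) {
    rlang::abort("the body cannot be the 'from' end of a body joint",
      class = "flapmode_config_error")
  }
  role_of <- stats::setNames(segments$role, labels)
  if (any(role_of[joints$from[is_ground]] != "leg")) {
    rlang::abort("ground springs may attach only to 'leg' segments",
      class = "flapmode_config_error")
  }

  M <- diag(segments$mass_kg, n, n)
  K <- matrix(0, n, n)
  idx <- stats::setNames(seq_len(n), labels)
  b <- idx[[body]]
  for (j in seq_len(nrow(joints))) {
    i <- idx[[joints$from[j]]]
    k <- joints$stiffness[j]
    if (is_ground[j]) {
      K[i, i] <- K[i, i] + k
    } else {
      K[b, b] <- K[b, b] + k
      K[i, i] <- K[i, i] + k
      K[b, i] <- K[b, i] - k
      K[i, b] <- K[i, b] - k
    }
  }

  ground_k <- stats::setNames(numeric(0), character(0))
  if (any(is_ground)) {
    gk <- tapply(joints$stiffness[is_ground], joints$from[is_ground], sum)
    ground_k <- stats::setNames(as.numeric(gk), names(gk))
  }

  pairs <- list()
  for (r in unique(segments$role[segments$role != "body"])) {
    l <- which(segments$role == r & segments$side == "left")
    rr <- which(segments$role == r & segments$side == "right")
    for (k in seq_len(min(length(l), length(rr)))) {
      pairs[[length(pairs) + 1L]] <- c(l[k], rr[k])
    }
  }

  structure(list(
    n_dof = n,
    mass_matrix = M,
    stiffness_matrix = K,
    dof_labels = labels,
    symmetry_pairs = pairs,
    ground_stiffness = ground_k,
    total_mass = sum(segments$mass_kg),
    rigid = all(joints$stiffness == 0),
    segments = segments,
    joints = joints
  ), class = "lumped_model")
}

#' @export
print.lumped_model <- function(x, ...) {
  cat("<lumped_model> ", x$n_dof, " vertical DOFs, total mass ",
    format(x$total_mass), " kg\n", sep = "")
  cat("  DOFs: ", paste(x$dof_labels, collapse = ", "), "\n", sep = "")
  cat("  ground springs: ",
    if (length(x$ground_stiffness) == 0) "none" else
      paste0(names(x$ground_stiffness), " (", x$ground_stiffness, " N/m)",
        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate an assembled lumped model
#'
#' Checks the structural invariants an assembled model must satisfy:
#' symmetric stiffness matrix, positive masses, positive (semi)definiteness,
#' and counts rigid-body modes (the dimension of the stiffness null space --
#' ungrounded models translate freely and have at least one).
#'
#' @param model A [lumped_model()].
#' @param asym_tol Relative asymmetry beyond which validation fails hard.
#'
#' @return A tibble with one row per check: `check`, `value`, `pass`.
#'   An asymmetric stiffness matrix raises an error; a model with rigid-body
#'   modes passes with a warning.
#' @export
validate_model <- function(model, asym_tol = 1e-9) {
  stopifnot(inherits(model, "lumped_model"))
  K <- model$stiffness_matrix
  M <- model$mass_matrix
  kscale <- max(abs(K), 1)
  asym <- max(abs(K - t(K))) / kscale
  if (asym > asym_tol) {
    rlang::abort(sprintf(
      "stiffness matrix is asymmetric (relative asymmetry %.3g > %.3g)",
      asym, asym_tol), class = "flapmode_validation_error")
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  n_rigid <- sum(abs(ev) < 1e-9 * kscale)
  pos_def <- all(ev > 1e-9 * kscale)
  pos_semidef <- all(ev > -1e-9 * kscale)
  mass_ok <- all(diag(M) > 0)
  if (n_rigid > 0) {
    rlang::warn(sprintf(
      "model has %d rigid-body mode(s): no ground spring restrains vertical translation",
      n_rigid))
  }
  tibble::tibble(
    check = c("stiffness_symmetric", "mass_positive", "stiffness_positive_definite",
      "stiffness_positive_semidefinite", "rigid_body_modes", "total_mass_kg"),
    value = c(asym, as.numeric(mass_ok), as.numeric(pos_def),
      as.numeric(pos_semidef), n_rigid, model$total_mass),
    pass = c(TRUE, mass_ok, pos_def || n_rigid > 0, pos_semidef, TRUE, TRUE)
  )
}

#' Dump a model matrix as CSV
#'
#' Writes the mass or stiffness matrix with DOF labels as the header row.
#'
#' @param model A [lumped_model()].
#' @param path Output file path.
#' @param which `"stiffness"` or `"mass"`.
#' @return The path, invisibly.
#' @export
write_matrix_csv <- function(model, path, which = c("stiffness", "mass")) {
  which <- match.arg(which)
  mat <- switch(which, stiffness = model$stiffness_matrix,
    mass = model$mass_matrix)
  colnames(mat) <- model$dof_labels
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}
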