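#' Interval box over uncertain model parameters
#'
#' Fossil-derived masses, stiffnesses and step lengths are only known as
#' ranges, so results are propagated as intervals rather than points.
#' Parameters are named by what they touch:
#' `"mass:<segment label>"` (kg), `"stiffness:<from>:<to>"` (N/m),
#' `"mass_scale"` (dimensionless factor on every segment mass) and
#' `"step_length"` (m).
#'
#' @param ... Named length-2 numeric vectors `c(low, high)`.
#' @return A tibble of class `interval_box`: `parameter`, `low`, `high`.
#' @export
#' @examples
#' interval_box(mass_scale = c(3, 7) / 5, step_length = c(0.30, 0.70))
interval_box <- function(...) {
  args <- list(...)
  if (length(args) == 0 || is.null(names(args)) || any(names(args) == "")) {
    rlang::abort("interval_box() needs named c(low, high) arguments",
      class = "flapmode_config_error")
  }
  lows <- vapply(args, `[`, numeric(1), 1)
  highs <- vapply(args, `[`, numeric(1), 2)
  if (any(lows > highs)) {
    rlang::abort("interval low must be <= high", class = "flapmode_validation_error")
  }
  phys <- grepl("^(mass|stiffness|mass_scale|step_length)", names(args))
  if (any(lows[phys] <= 0)) {
    rlang::abort("physical parameters must stay positive (low > 0)",
      class = "flapmode_validation_error")
  }
  out <- tibble::tibble(parameter = names(args), low = unname(lows),
    high = unname(highs))
  class(out) <- c("interval_box", class(out))
  out
}

# Rebuild a model with parameters set to the values of a named point.
apply_parameter_point <- function(model, point) {
  seg <- model$segments
  jnt <- model$joints
  for (nm in names(point)) {
    v <- point[[nm]]
    if (nm == "mass_scale") {
      seg$mass_kg <- seg$mass_kg * v
    } else if (startsWith(nm, "mass:")) {
      lab <- sub("^mass:", "", nm)
      i <- match(lab, seg$label)
      if (is.na(i)) {
        rlang::abort(paste0("box parameter names unknown segment: ", lab),
          class = "flapmode_config_error")
      }
      seg$mass_kg[i] <- v
    } else if (startsWith(nm, "stiffness:")) {
      parts <- strsplit(sub("^stiffness:", "", nm), ":", fixed = TRUE)[[1]]
      i <- which(jnt$from == parts[1] & jnt$to == parts[2])
      if (length(i) == 0) {
        rlang::abort(paste0("box parameter names unknown joint: ", nm),
          class = "flapmode_config_error")
      }
      jnt$stiffness[i] <- v
    } else if (nm == "step_length") {
      # gait parameter; handled by interval_speed_bounds
    } else {
      rlang::abort(paste0("unknown box parameter: ", nm),
        class = "flapmode_config_error")
    }
  }
  attr(seg, "total_mass") <- sum(seg$mass_kg)
  lumped_model(seg, jnt)
}

# Frequencies of a perturbed model matched to the nominal mode order by
# mass-weighted shape overlap (greedy assignment on the MAC-like matrix).
matched_frequencies <- function(model_pert, nominal_res) {
  res <- solve_modes(model_pert)
  Mn <- nominal_res$model$mass_matrix
  O <- abs(crossprod(res$mode_shapes, Mn %*% nominal_res$mode_shapes))
  n <- ncol(O)
  f <- rep(NA_real_, n)
  for (step in seq_len(n)) {
    k <- arrayInd(which.max(O), dim(O))
    i <- k[1]; j <- k[2]
    f[j] <- res$freq_hz[i]
    O[i, ] <- -Inf
    O[, j] <- -Inf
  }
  f
}

#' Interval bounds on natural frequencies
#'
#' Propagates an [interval_box()] to per-mode frequency intervals two ways:
#' *vertex* enumeration evaluates every corner of the box (an outer bound
#' whenever each frequency is monotone in each parameter over the box,
#' which holds for the physical ranges treated here), and seeded uniform
#' *sampling* gives an inner bound. `"combined"` reports the union and lets
#' disagreement beyond the sampling resolution flag non-monotone behavior.
#' Across the box, modes are tracked by shape overlap with the nominal
#' modes, not raw eigenvalue order, so crossing branches do not scramble
#' the intervals.
#'
#' @param model The nominal [lumped_model()].
#' @param box An [interval_box()] (its `step_length` row, if any, is left
#'   to [interval_speed_bounds()]).
#' @param method `"combined"` (default), `"vertex"` or `"sampling"`.
#'   Vertex enumeration is refused for more than 16 parameters.
#' @param n_samples Uniform samples for the sampling pass.
#' @param seed Integer seed for sampling.
#' @return A tibble of class `interval_result`: `mode`, `f_nominal`,
#'   `f_lo`, `f_hi` (the method's outer interval) and, for
#'   `method = "combined"`, `f_lo_inner`, `f_hi_inner` from sampling.
#'   Attributes: `method`, `n_samples`, `seed`, `box`.
#' @export
#' @examples
#' interval_modal_bounds(caudipteryx_model(),
#'   interval_box(mass_scale = c(0.6, 1.4)), n_samples = 100)
interval_modal_bounds <- function(model, box,
                                  method = c("combined", "vertex", "sampling"),
                                  n_samples = 2000, seed = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "lumped_model"), inherits(box, "interval_box"))
  pbox <- box[box$parameter != "step_length", , drop = FALSE]
  p <- nrow(pbox)
  if (p == 0) {
    rlang::abort("box contains no model parameters",
      class = "flapmode_config_error")
  }
  if (method %in% c("vertex", "combined") && p > 16) {
    rlang::abort(sprintf(
      "vertex enumeration over %d parameters (2^%d corners) refused; use method = 'sampling'",
      p, p), class = "flapmode_validation_error")
  }
  nominal <- solve_modes(model)
  n <- length(nominal$freq_hz)

  eval_point <- function(vals) {
    matched_frequencies(apply_parameter_point(model,
      stats::setNames(as.list(vals), pbox$parameter)), nominal)
  }

  fmat <- matrix(nominal$freq_hz, nrow = 1)  # nominal always included
  vert_mat <- NULL
  if (method %in% c("vertex", "combined")) {
    corners <- as.matrix(expand.grid(rep(list(c(1, 2)), p)))
    vert_mat <- t(apply(corners, 1, function(sel) {
      vals <- ifelse(sel == 1, pbox$low, pbox$high)
      eval_point(vals)
    }))
  }
  samp_mat <- NULL
  if (method %in% c("sampling", "combined")) {
    local_seed(seed)
    samp_mat <- t(vapply(seq_len(n_samples), function(s) {
      vals <- stats::runif(p, pbox$low, pbox$high)
      eval_point(vals)
    }, numeric(n)))
  }
  outer_mat <- rbind(fmat, vert_mat, samp_mat)
  out <- tibble::tibble(
    mode = seq_len(n),
    f_nominal = nominal$freq_hz,
    f_lo = apply(outer_mat, 2, min),
    f_hi = apply(outer_mat, 2, max)
  )
  if (method == "combined") {
    inner <- rbind(fmat, samp_mat)
    out$f_lo_inner <- apply(inner, 2, min)
    out$f_hi_inner <- apply(inner, 2, max)
  }
  class(out) <- c("interval_result", class(out))
  attr(out, "method") <- method
  attr(out, "n_samples") <- if (is.null(samp_mat)) 0L else n_samples
  attr(out, "seed") <- seed
  attr(out, "box") <- box
  attr(out, "flapping_mode") <- {
    cls <- classify_modes(nominal)
    if (any(cls$flapping)) cls$mode[cls$flapping][
      which.max(cls$effective_mass[cls$flapping])] else NA_integer_
  }
  out
}

#' Interval bounds on resonance speeds
#'
#' Multiplies per-mode frequency intervals by the stride-length interval
#' (the exact interval product for positive intervals:
#' `[f_lo s_lo, f_hi s_hi]`). The stride interval comes from the
#' `step_length` row of a box (stride = 2 x step under the default
#' convention) or collapses to the gait's point stride.
#'
#' @param modal_bounds An `interval_result` from [interval_modal_bounds()].
#' @param gait_box An [interval_box()] containing `step_length`, or `NULL`.
#' @param gait A [gait_params()] supplying the convention (and the point
#'   stride when `gait_box` has no `step_length`).
#' @return The `interval_result` with `v_lo`, `v_hi` (and inner bounds when
#'   present) added, plus attribute `flapping_window` = the speed interval
#'   of the nominal flapping mode.
#' @export
interval_speed_bounds <- function(modal_bounds, gait_box = NULL,
                                  gait = caudipteryx_gait()) {
  stopifnot(inherits(modal_bounds, "interval_result"))
  stride <- rep(gait_cycle_length(gait), 2)
  if (!is.null(gait_box)) {
    row <- gait_box[gait_box$parameter == "step_length", , drop = FALSE]
    if (nrow(row) == 1) {
      fac <- gait_cycle_length(gait) / gait$step_length
      stride <- c(row$low, row$high) * fac
    }
  }
  out <- dplyr::mutate(modal_bounds,
    v_lo = .data$f_lo * stride[1],
    v_hi = .data$f_hi * stride[2],
    v_nominal = .data$f_nominal * gait_cycle_length(gait)
  )
  if ("f_lo_inner" %in% names(out)) {
    out$v_lo_inner <- out$f_lo_inner * stride[1]
    out$v_hi_inner <- out$f_hi_inner * stride[2]
  }
  class(out) <- unique(c("interval_result", class(out)))
  for (a in c("method", "n_samples", "seed", "box", "flapping_mode")) {
    attr(out, a) <- attr(modal_bounds, a)
  }
  fm <- attr(modal_bounds, "flapping_mode")
  attr(out, "flapping_window") <- if (!is.na(fm)) {
    c(out$v_lo[fm], out$v_hi[fm])
  } else c(NA_real_, NA_real_)
  out
}
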