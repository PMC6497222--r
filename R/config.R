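#' Read a model-spec config file
#'
#' Loads a YAML (or JSON) model specification: a `segments` list (label,
#' mass_kg, role, side), a `joints` list (from, to, stiffness_N_per_m,
#' damping_ratio) and an optional `gait` block (step_length_m,
#' stride_length_m, froude_max, hip_height_m, gravity, excitation).
#' Configurations round-trip bit-exactly through [write_model_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `model_config` with elements `segments` (tibble),
#'   `joints` (tibble) and `gait` ([gait_params()] or `NULL`).
#' @seealso [write_model_config()], [lumped_model()]
#' @export
#' @examples
#' cfg <- read_model_config(
#'   system.file("extdata", "caudipteryx.yaml", package = "flapmode"))
#' model <- lumped_model(cfg$segments, cfg$joints)
read_model_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
      class = "flapmode_config_error")
  }
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    rlang::abort(paste0("malformed config '", path, "': ",
      conditionMessage(e)), class = "flapmode_config_error")
  })
  for (block in c("segments", "joints")) {
    if (is.null(raw[[block]])) {
      rlang::abort(paste0("config is missing the '", block, "' block"),
        class = "flapmode_config_error")
    }
  }
  get_field <- function(rows, field, default = NULL) {
    vapply(rows, function(r) {
      v <- r[[field]]
      if (is.null(v)) {
        if (is.null(default)) {
          rlang::abort(paste0("config entry is missing field '", field, "'"),
            class = "flapmode_config_error")
        }
        v <- default
      }
      v
    }, if (field %in% c("label", "role", "side", "from", "to"))
      character(1) else numeric(1))
  }
  segments <- segment_set(
    label = get_field(raw$segments, "label"),
    mass_kg = get_field(raw$segments, "mass_kg"),
    role = get_field(raw$segments, "role"),
    side = get_field(raw$segments, "side", default = "center")
  )
  joints <- joint_set(
    from = get_field(raw$joints, "from"),
    to = get_field(raw$joints, "to"),
    stiffness = get_field(raw$joints, "stiffness_N_per_m"),
    damping_ratio = get_field(raw$joints, "damping_ratio", default = 0)
  )
  gait <- NULL
  if (!is.null(raw$gait)) {
    g <- raw$gait
    if (is.null(g$step_length_m)) {
      rlang::abort("gait block is missing 'step_length_m'",
        class = "flapmode_config_error")
    }
    gait <- gait_params(
      step_length = g$step_length_m,
      stride_length = g$stride_length_m %||% (2 * g$step_length_m),
      froude_max = g$froude_max %||% 17,
      hip_height = g$hip_height_m,
      gravity = g$gravity %||% 9.81,
      excitation = g$excitation %||% "stride"
    )
  }
  structure(list(segments = segments, joints = joints, gait = gait),
    class = "model_config")
}

#' Write a model-spec config file
#'
#' Serializes a model configuration to YAML with numerics rendered at full
#' precision, so `load -> save -> load` reproduces the model bit-exactly.
#'
#' @param config A `model_config` (from [read_model_config()]), or a
#'   [lumped_model()] (its segment/joint tables are used; pass `gait` too).
#' @param path Output path.
#' @param gait Optional [gait_params()] when `config` is a `lumped_model`.
#' @return The path, invisibly.
#' @export
write_model_config <- function(config, path, gait = NULL) {
  if (inherits(config, "lumped_model")) {
    config <- structure(list(segments = config$segments,
      joints = config$joints, gait = gait), class = "model_config")
  }
  seg <- config$segments
  jnt <- config$joints
  out <- list(
    segments = lapply(seq_len(nrow(seg)), function(i) list(
      label = seg$label[i], mass_kg = seg$mass_kg[i],
      role = seg$role[i], side = seg$side[i])),
    joints = lapply(seq_len(nrow(jnt)), function(i) list(
      from = jnt$from[i], to = jnt$to[i],
      stiffness_N_per_m = jnt$stiffness[i],
      damping_ratio = jnt$damping_ratio[i]))
  )
  if (!is.null(config$gait)) {
    g <- config$gait
    out$gait <- list(step_length_m = g$step_length, stride_length_m = g$stride_length,
      froude_max = g$froude_max, hip_height_m = g$hip_height,
      gravity = g$gravity, excitation = g$excitation)
    out$gait <- out$gait[!vapply(out$gait, is.null, logical(1))]
  }
  handlers <- list(numeric = function(v) {
    r <- fmt_num(v)
    class(r) <- "verbatim"
    r
  })
  writeLines(yaml::as.yaml(out, handlers = handlers), path)
  invisible(path)
}
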