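#' Run the full modal-analysis pipeline on a model config
#'
#' Orchestrates assemble -> validate -> eigensolve -> participation ->
#' classification -> resonance-speed table, with optional interval
#' propagation and a forced-response summary. Everything downstream is a
#' deterministic function of the config and the seed.
#'
#' @param config Path to a model config file, or a `model_config` from
#'   [read_model_config()].
#' @param seed Integer seed used for any sampling stage.
#' @param speeds Compute the resonance-speed table (requires a gait block;
#'   an informative error names the missing keys otherwise).
#' @param intervals Optional [interval_box()] to propagate.
#' @param forced Optional list of arguments for
#'   [simulate_running_response()] (e.g. `list(speed = 2, duration = 12)`);
#'   a [damping_spec()] may be supplied as element `damping`.
#' @return An object of class `analysis_report`: list with `model_summary`,
#'   `modal_table`, `speed_table`, `interval_table`, `forced_summary` and
#'   `provenance` (config hash, seed, package version, timestamp).
#' @export
#' @examples
#' cfg <- system.file("extdata", "caudipteryx.yaml", package = "flapmode")
#' report <- run_analysis(cfg)
#' report$modal_table
run_analysis <- function(config, seed = 0L, speeds = TRUE, intervals = NULL,
                         forced = NULL) {
  if (is.character(config)) {
    hash <- unname(tools::md5sum(config))
    config <- read_model_config(config)
  } else if (inherits(config, "model_config")) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    write_model_config(config, tmp)
    hash <- unname(tools::md5sum(tmp))
  } else {
    rlang::abort("config must be a path or a model_config",
      class = "flapmode_config_error")
  }

  stage <- "assemble"
  report <- tryCatch({
    model <- lumped_model(config$segments, config$joints)
    stage <- "validate"
    validation <- validate_model(model)
    stage <- "solve"
    res <- solve_modes(model)
    stage <- "classify"
    modal_table <- classify_modes(res)
    if (abs(sum(res$effective_mass) - model$total_mass) >
        1e-8 * model$total_mass) {
      rlang::abort("effective-mass completeness violated",
        class = "flapmode_numerical_error")
    }
    speed_table <- NULL
    if (isTRUE(speeds)) {
      stage <- "speeds"
      if (is.null(config$gait)) {
        rlang::abort(paste0(
          "speed mapping requested but the config has no gait block; ",
          "add gait: {step_length_m, froude_max, hip_height_m}"),
          class = "flapmode_config_error")
      }
      speed_table <- resonance_speed_table(res, config$gait)
    }
    interval_table <- NULL
    if (!is.null(intervals)) {
      stage <- "intervals"
      ib <- interval_modal_bounds(model, intervals, n_samples = 500,
        seed = seed)
      interval_table <- if (!is.null(config$gait)) {
        interval_speed_bounds(ib, intervals, gait = config$gait)
      } else ib
    }
    forced_summary <- NULL
    if (!is.null(forced)) {
      stage <- "forced_response"
      damping <- forced$damping %||% damping_spec(ratio = 0.05)
      forced$damping <- NULL
      sim <- do.call(simulate_running_response,
        c(list(model = model, damping = damping, gait = config$gait,
          seed = seed), forced))
      forced_summary <- tibble::tibble(
        dof = model$dof_labels,
        steady_amplitude = unname(attr(sim, "steady_amplitude"))
      )
      attr(forced_summary, "metadata") <- attr(sim, "metadata")
      attr(forced_summary, "wing_amplitude") <- attr(sim, "wing_amplitude")
    }
    list(
      model_summary = validation,
      modal_table = modal_table,
      speed_table = speed_table,
      interval_table = interval_table,
      forced_summary = forced_summary
    )
  }, flapmode_numerical_error = function(e) {
    rlang::abort(paste0("pipeline aborted at stage '", stage, "': ",
      conditionMessage(e)), class = "flapmode_pipeline_error")
  })
  report$provenance <- list(
    config_hash = hash,
    seed = as.integer(seed),
    version = as.character(utils::packageVersion("flapmode")),
    created = format(Sys.time(), tz = "UTC")
  )
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> config ", substr(x$provenance$config_hash, 1, 8),
    ", seed ", x$provenance$seed, "\n\nModal table:\n", sep = "")
  print(x$modal_table)
  if (!is.null(x$speed_table)) {
    cat("\nResonance speeds:\n")
    print(x$speed_table)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' JSON and CSV carry full numeric precision; the plain-text report rounds
#' to 4 significant digits and marks flapping modes with `*`.
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    rlang::abort(paste0("cannot write to directory: ", dir),
      class = "flapmode_config_error")
  }
  tables <- Filter(Negate(is.null), report[c("model_summary", "modal_table",
    "speed_table", "interval_table", "forced_summary")])
  files <- character(0)
  if (format == "json") {
    path <- file.path(dir, "report.json")
    payload <- c(lapply(tables, as.data.frame),
      list(provenance = report$provenance))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files <- path
  } else if (format == "csv") {
    for (nm in names(tables)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(tables[[nm]]), path, row.names = FALSE)
      files <- c(files, path)
    }
  } else {
    path <- file.path(dir, "report.txt")
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(
      "flapmode analysis report",
      paste0("config: ", report$provenance$config_hash,
        "  seed: ", report$provenance$seed,
        "  version: ", report$provenance$version), ""), con)
    for (nm in names(tables)) {
      tab <- as.data.frame(tables[[nm]])
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], signif, digits = 4)
      if (nm == "modal_table" && "flapping" %in% names(tab)) {
        tab$mark <- ifelse(tab$flapping, "*", "")
      }
      writeLines(paste0("## ", nm), con)
      utils::capture.output(print(tab, row.names = FALSE), file = con)
      writeLines("", con)
    }
    files <- path
  }
  invisible(files)
}
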