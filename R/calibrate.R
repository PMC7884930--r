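#' Calibration configuration
#'
#' Bundles everything one calibration run needs: where the model and
#' observation files live, the parameter set, the objective
#' specification, the optimiser options, an optional explicit method
#' override, and whether the specimens are calibrated as one group (a
#' single shared parameter set) or one run per specimen.
#'
#' @param model_dir directory of model-definition files.
#' @param data_dir directory of `.dat` files (default: `model_dir`).
#' @param output_dir where run artefacts are written.
#' @param parameters a [parameter_set()].
#' @param objective an [objective_spec()].
#' @param options an [optimiser_options()].
#' @param method optional explicit method identifier.
#' @param mode `"group"` or `"per_specimen"`.
#' @return a `calibration_config` object.
#' @export
calibration_config <- function(model_dir, data_dir = model_dir,
                               output_dir = file.path(model_dir, "results"),
                               parameters, objective,
                               options = optimiser_options(),
                               method = NULL,
                               mode = c("group", "per_specimen")) {
  mode <- match.arg(mode)
  stopifnot(inherits(parameters, "parameter_set"),
            inherits(objective, "objective_spec"),
            inherits(options, "optimiser_options"))
  structure(list(model_dir = model_dir, data_dir = data_dir,
                 output_dir = output_dir, parameters = parameters,
                 objective = objective, options = options,
                 method = method, mode = mode),
            class = "calibration_config")
}

#' Default calibration setup for a built-in case study
#'
#' Returns the per-case conventions: the bone greyscale case calibrates
#' the mapping slope with Brent over an RMS normalised-difference
#' objective (normal termination 0.1); the osteodisc case calibrates
#' (k1, k2) with L-BFGS-B over the group RMS load difference in newtons
#' (normal termination 5\% of the largest observed load, supplied when
#' `pairs` is given); the interface case calibrates (k_r, k_t) with
#' bounded least squares over normalised displacement residuals, one run
#' per specimen (normal termination 0.01).
#'
#' @param case case identifier.
#' @param pairs optional loaded pairs, used to scale the osteodisc
#'   normal-termination threshold to the data.
#' @param f_tol override of the case's normal-termination threshold;
#'   `NA` keeps the case default, `NULL` disables the check.
#' @return list with `parameters`, `objective`, `options`, `mode`.
#' @export
case_defaults <- function(case = c("bone_greyscale", "osteodisc_goh", "interface_slice"),
                          pairs = NULL, f_tol = NA) {
  case <- match.arg(case)
  out <- switch(case,
    bone_greyscale = list(
      parameters = parameter_set("slope", lower = 100, upper = 5000),
      objective = objective_spec("direct", "relative", "rms_over_models",
                                 "experimental_value"),
      options = optimiser_options(f_tol = 0.1, x_tol = 1e-6),
      mode = "group"),
    osteodisc_goh = list(
      parameters = parameter_set(c("k1", "k2"), initial = c(1, 20),
                                 lower = c(0.01, 1), upper = c(100, 500)),
      objective = objective_spec("direct", "difference", "rms_over_models"),
      options = optimiser_options(f_tol = NULL, fd_step = 1e-4),
      mode = "group"),
    interface_slice = list(
      parameters = parameter_set(c("k_r", "k_t"), initial = c(5, 5),
                                 lower = c(0.01, 0.01), upper = c(1000, 1000)),
      objective = objective_spec("least_squares", "relative",
                                 "concatenated_residuals", "max_experimental"),
      options = optimiser_options(f_tol = 0.01),
      mode = "per_specimen"))
  if (case == "osteodisc_goh" && !is.null(pairs)) {
    max_load <- max(vapply(pairs, function(p) max(abs(p$obs$payload$y)), numeric(1)))
    out$options$f_tol <- 0.05 * max_load
  }
  if (!identical(f_tol, NA)) out$options$f_tol <- f_tol
  out
}

#' Run a calibration end to end
#'
#' Loads the model/observation pairs (erroring on unpaired files before
#' any model runs), dispatches the optimisation method, minimises,
#' estimates confidence intervals, and writes the run artefacts to the
#' output directory: `summary(.json)`, `history(.txt)` when enabled,
#' `confidence(.json)` when computable, and `run.log`. In
#' `"per_specimen"` mode one full calibration is run per pair and the
#' artefacts carry the specimen name.
#'
#' @param config a [calibration_config()].
#' @param level confidence level for the interval report.
#' @return for group mode, a list with `result`, `confidence`,
#'   `artefacts`; for per-specimen mode, a named list of those per
#'   specimen.
#' @export
run_calibration <- function(config, level = 0.95) {
  stopifnot(inherits(config, "calibration_config"))
  pairs <- load_pairs(config$model_dir, config$data_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(fmt, ...) {
    writeLines(sprintf("[%s] %s", "calibfe", sprintf(fmt, ...)), log_con)
  }
  logmsg("loaded %d specimen pair(s) from %s", length(pairs), config$model_dir)

  run_one <- function(pairs, tag = NULL) {
    result <- minimise(pairs, config$objective, config$parameters,
                       config$options, method = config$method)
    logmsg("%s: %s terminated (%s) at objective %.6g after %d evaluations",
           tag %||% "group", result$method, result$termination,
           result$objective_value, result$n_evaluations)
    confidence <- tryCatch(confidence_intervals(result, level = level),
                           error = function(e) {
                             logmsg("confidence intervals unavailable: %s",
                                    conditionMessage(e))
                             NULL
                           })
    stem <- if (is.null(tag)) "" else paste0(tag, "_")
    artefacts <- c(summary = file.path(config$output_dir,
                                       paste0(stem, "summary.json")))
    write_summary(result, artefacts[["summary"]], confidence = confidence)
    if (!is.null(result$history)) {
      artefacts[["history"]] <- file.path(config$output_dir,
                                          paste0(stem, "history.txt"))
      write_history(result, artefacts[["history"]])
    }
    if (!is.null(confidence)) {
      artefacts[["confidence"]] <- file.path(config$output_dir,
                                             paste0(stem, "confidence.json"))
      jsonlite::write_json(list(level = confidence$level,
                                residual_variance = confidence$residual_variance,
                                covariance = confidence$covariance,
                                intervals = confidence$intervals),
                           artefacts[["confidence"]], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(result = result, confidence = confidence, artefacts = artefacts)
  }

  if (config$mode == "group") {
    out <- run_one(pairs)
  } else {
    out <- lapply(pairs, function(p) run_one(list(p), tag = p$obs$name))
    names(out) <- vapply(pairs, function(p) p$obs$name, character(1))
  }
  logmsg("artefacts written to %s", config$output_dir)
  out
}

#' Read a calibration configuration file
#'
#' YAML with keys `model_dir`, `data_dir`, `output_dir` (paths relative
#' to the config file), `parameters` (`names`, optional `initial`,
#' `lower`, `upper`), `objective`, `options`, optional `method`, and
#' `mode`.
#'
#' @param path config file path.
#' @return a [calibration_config()].
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p, default) {
    if (is.null(p)) return(default)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  pars <- doc$parameters
  obj <- doc$objective %||% list()
  opt <- doc$options %||% list()
  model_dir <- rel(doc$model_dir, base)
  calibration_config(
    model_dir = model_dir,
    data_dir = rel(doc$data_dir, model_dir),
    output_dir = rel(doc$output_dir, file.path(model_dir, "results")),
    parameters = parameter_set(pars$names, initial = pars$initial,
                               lower = pars$lower, upper = pars$upper),
    objective = objective_spec(
      comparison = obj$comparison %||% "direct",
      error_form = obj$error_form %||% "difference",
      aggregation = obj$aggregation %||% "rms_over_models",
      normalisation_reference = obj$normalisation_reference %||% "experimental_value"),
    options = optimiser_options(
      max_iterations = opt$max_iterations %||% 200L,
      f_tol = opt$f_tol,
      x_tol = opt$x_tol %||% 1e-8,
      g_tol = opt$g_tol %||% 1e-8,
      fd_step = opt$fd_step %||% 1e-6,
      history = opt$history %||% TRUE),
    method = doc$method,
    mode = doc$mode %||% "group")
}

#' Write a calibration configuration file
#'
#' Inverse of [read_config()]; the round trip is lossless for every
#' field (paths are written as given).
#'
#' @param config a [calibration_config()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "calibration_config"))
  p <- config$parameters
  doc <- list(model_dir = config$model_dir, data_dir = config$data_dir,
              output_dir = config$output_dir,
              parameters = Filter(Negate(is.null),
                                  list(names = p$names, initial = p$initial,
                                       lower = p$lower, upper = p$upper)),
              objective = unclass(config$objective),
              options = Filter(Negate(is.null), unclass(config$options)),
              method = config$method, mode = config$mode)
  yaml::write_yaml(Filter(Negate(is.null), doc), path, precision = 17L)
  invisible(path)
}
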