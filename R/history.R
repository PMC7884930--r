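#' Write the optimisation history to a text file
#'
#' Tab-separated with a header line and one row per recorded objective
#' evaluation in fixed column order: evaluation index (the initial point
#' is 0), the parameter values, then the objective value. Re-running
#' overwrites the file; histories never append.
#'
#' @param result an `optimisation_result` produced with history enabled.
#' @param path destination text file.
#' @return `path`, invisibly.
#' @export
write_history <- function(result, path) {
  stopifnot(inherits(result, "optimisation_result"))
  if (is.null(result$history)) {
    stop("no history recorded: run minimise() with history enabled")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(result$history), collapse = "\t"), con)
  apply(result$history, 1L, function(row) {
    writeLines(paste(formatC(row, format = "g", digits = 17), collapse = "\t"), con)
  })
  invisible(path)
}

#' Read a history file back into a data frame
#' @param path a file written by [write_history()].
#' @return data frame with `iter`, parameter columns and `objective`.
#' @export
read_history <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Serialise an optimisation result summary as JSON
#'
#' Writes every result field except the (separately stored) history:
#' final parameters, objective value and kind, method, counts,
#' termination reason and message, Jacobian and Hessian estimates, and
#' the final residual vector.
#'
#' @param result an `optimisation_result`.
#' @param path destination `.json` file.
#' @param confidence optional `confidence_report` to embed.
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path, confidence = NULL) {
  stopifnot(inherits(result, "optimisation_result"))
  doc <- list(
    final_params = as.list(stats::setNames(as.numeric(result$final_params),
                                           result$parameter_names)),
    objective_value = result$objective_value,
    objective_kind = result$objective_kind,
    method = result$method,
    n_iterations = result$n_iterations,
    n_evaluations = result$n_evaluations,
    termination = result$termination,
    message = result$message,
    jacobian = result$jacobian,
    hessian = result$hessian,
    residuals = result$residuals
  )
  if (!is.null(confidence)) {
    doc$confidence <- list(level = confidence$level,
                           residual_variance = confidence$residual_variance,
                           covariance = confidence$covariance,
                           intervals = confidence$intervals)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
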