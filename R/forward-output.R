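#' Forward-model output container
#'
#' Every forward model returns one of three payload kinds -- a scalar, an
#' ordered list of reals, or a curve -- or a failure sentinel. A failed
#' output is data, not an error: group calibration excludes failed
#' specimens from the objective instead of aborting, so a solver that does
#' not converge at some parameter set never crashes the optimisation.
#'
#' @param value scalar, numeric vector, or `calib_curve`.
#' @param kind one of `"scalar"`, `"list"`, `"curve"`; inferred from
#'   `value` when missing.
#' @return a `forward_output` object with fields `kind`, `value`, `failed`.
#' @export
forward_output <- function(value, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (is_curve(value)) "curve" else if (length(value) == 1L) "scalar" else "list"
  }
  kind <- match.arg(kind, c("scalar", "list", "curve"))
  if (kind == "curve" && !is_curve(value)) stop("curve output requires a calib_curve value")
  if (kind == "scalar" && length(value) != 1L) stop("scalar output requires length-1 value")
  if (kind != "curve") value <- as.numeric(value)
  structure(list(kind = kind, value = value, failed = FALSE),
            class = "forward_output")
}

#' Failure sentinel for a forward solve
#'
#' @param kind the payload kind the model would have produced.
#' @param message diagnostic string (singular system, overflow, ...).
#' @return a `forward_output` with `failed = TRUE` and no usable payload.
#' @export
forward_failure <- function(kind, message = "solver failure") {
  kind <- match.arg(kind, c("scalar", "list", "curve"))
  structure(list(kind = kind, value = NULL, failed = TRUE, message = message),
            class = "forward_output")
}

#' @export
print.forward_output <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<forward output: FAILED (%s)>\n", x$message))
  } else {
    cat(sprintf("<forward output: %s>\n", x$kind))
  }
  invisible(x)
}

is_forward_output <- function(x) inherits(x, "forward_output")
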