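#' Paired (x, y) curve
#'
#' A curve is two equal-length numeric vectors, the abscissa strictly
#' increasing. Used for force-displacement data (x displacement in mm,
#' y load in N) but agnostic to units.
#'
#' @param x numeric, strictly increasing, length >= 2.
#' @param y numeric, same length as `x`.
#' @return an object of class `calib_curve` with fields `x` and `y`.
#' @export
curve_data <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L) stop("curve needs at least 2 points")
  if (length(x) != length(y)) stop("curve x and y must have the same length")
  if (anyNA(x) || anyNA(y)) stop("curve contains missing values")
  if (any(diff(x) <= 0)) stop("curve x must be strictly increasing")
  structure(list(x = x, y = y), class = "calib_curve")
}

#' @export
print.calib_curve <- function(x, ...) {
  cat(sprintf("<curve: %d points, x in [%g, %g]>\n",
              length(x$x), x$x[1], x$x[length(x$x)]))
  invisible(x)
}

is_curve <- function(obj) inherits(obj, "calib_curve")

#' Interpolate two curves onto a common grid
#'
#' Restricts both curves to the overlap of their x-ranges, then resamples
#' the coarser curve onto the grid of whichever curve has more samples
#' within the overlap (ties go to the experimental grid, preserving the
#' measured abscissae). Linear interpolation only; no extrapolation ever
#' occurs because the target grid lies inside both x-ranges.
#'
#' @param model a `calib_curve` of computed values.
#' @param experiment a `calib_curve` of measured values.
#' @param name specimen identifier used in error messages.
#' @return list with `y_model`, `y_exp` (equal-length numeric) and the
#'   common grid `x`.
#' @export
interpolate_to_common_grid <- function(model, experiment, name = "<specimen>") {
  stopifnot(is_curve(model), is_curve(experiment))
  lo <- max(model$x[1], experiment$x[1])
  hi <- min(model$x[length(model$x)], experiment$x[length(experiment$x)])
  if (lo > hi) {
    stop(sprintf("specimen '%s': model and experimental curves have no overlapping x-range", name))
  }
  in_overlap <- function(cv) cv$x >= lo & cv$x <= hi
  n_mod <- sum(in_overlap(model))
  n_exp <- sum(in_overlap(experiment))
  # denser grid wins; tie broken toward the experimental grid
  if (n_mod > n_exp) {
    grid <- model$x[in_overlap(model)]
  } else {
    grid <- experiment$x[in_overlap(experiment)]
  }
  if (length(grid) < 2L) {
    stop(sprintf("specimen '%s': fewer than 2 points in the x-overlap [%g, %g]", name, lo, hi))
  }
  resample <- function(cv) {
    # exact passthrough when the grid is already the curve's own grid
    if (length(cv$x) == length(grid) && all(cv$x == grid)) return(cv$y)
    stats::approx(cv$x, cv$y, xout = grid, method = "linear", rule = 1)$y
  }
  list(x = grid, y_model = resample(model), y_exp = resample(experiment))
}
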