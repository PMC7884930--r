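#' Parameter set for a calibration
#'
#' @param names character vector of unique parameter names.
#' @param initial initial values; may be omitted only for univariate
#'   scalar problems with bounds (Brent brackets the interval directly).
#' @param lower,upper optional per-parameter bounds; a lower bound of 0
#'   encodes the positivity constraint of material parameters.
#' @return a `parameter_set` object.
#' @export
parameter_set <- function(names, initial = NULL, lower = NULL, upper = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("parameter names must be unique")
  p <- length(names)
  if (!is.null(initial)) {
    initial <- as.numeric(initial)
    if (length(initial) != p) stop("initial values must match parameter names")
  }
  if (!is.null(lower)) lower <- rep_len(as.numeric(lower), p)
  if (!is.null(upper)) upper <- rep_len(as.numeric(upper), p)
  if (!is.null(lower) && !is.null(upper) && any(lower > upper)) {
    stop("lower bounds exceed upper bounds")
  }
  if (!is.null(initial) && !is.null(lower) && any(initial < lower)) {
    stop("initial values below lower bounds")
  }
  if (!is.null(initial) && !is.null(upper) && any(initial > upper)) {
    stop("initial values above upper bounds")
  }
  structure(list(names = names, initial = initial, lower = lower,
                 upper = upper, n = p, bounded = !is.null(lower) || !is.null(upper)),
            class = "parameter_set")
}

#' Optimiser options
#'
#' @param max_iterations iteration cap of the underlying algorithm.
#' @param f_tol absolute objective threshold for normal termination: the
#'   run stops as soon as the (scalar) objective falls below it. `NULL`
#'   disables the check.
#' @param x_tol parameter-variation termination tolerance.
#' @param g_tol gradient termination tolerance.
#' @param fd_step step size for numerical gradients/Jacobians.
#' @param history record one row per objective evaluation (the initial
#'   point is row 0) for [write_history()].
#' @return an `optimiser_options` object.
#' @export
optimiser_options <- function(max_iterations = 200L, f_tol = NULL,
                              x_tol = 1e-8, g_tol = 1e-8, fd_step = 1e-6,
                              history = TRUE) {
  if (!is.null(f_tol) && f_tol < 0) stop("f_tol must be non-negative")
  if (x_tol <= 0 || g_tol <= 0 || fd_step <= 0) {
    stop("tolerances and fd_step must be strictly positive")
  }
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  structure(list(max_iterations = as.integer(max_iterations), f_tol = f_tol,
                 x_tol = x_tol, g_tol = g_tol, fd_step = fd_step,
                 history = isTRUE(history)),
            class = "optimiser_options")
}

#' Optimisation-method dispatch
#'
#' Returns the method for a problem shape, following the toolbox's
#' dispatch table: univariate scalar problems use Brent (bounded or not);
#' multivariate scalar objectives use L-BFGS-B when bounded and conjugate
#' gradient otherwise; multivariate functional (vector-residual)
#' objectives use the trust-region-reflective bounded least-squares cell
#' when bounded and Levenberg-Marquardt otherwise. A univariate
#' functional objective has no dispatch cell and errors.
#'
#' @param n_params number of calibrated parameters (>= 1).
#' @param objective_kind `"scalar"` or `"functional"`.
#' @param bounded are parameter bounds declared?
#' @return method identifier string.
#' @export
select_method <- function(n_params, objective_kind = c("scalar", "functional"),
                          bounded = FALSE) {
  objective_kind <- match.arg(objective_kind)
  if (n_params < 1) stop("n_params must be at least 1")
  if (n_params == 1L) {
    if (objective_kind == "functional") {
      stop("no method is defined for a univariate functional objective")
    }
    return("brent")
  }
  if (objective_kind == "scalar") {
    if (bounded) "l-bfgs-b" else "conjugate-gradient"
  } else {
    if (bounded) "trust-region-reflective" else "levenberg-marquardt"
  }
}

# condition used to stop an optimiser as soon as the objective drops
# below f_tol (normal termination on the objective criterion); signalled
# with stop() so it unwinds through the backend's C code
stop_condition <- function(reason) {
  structure(class = c("calibfe_stop", "error", "condition"),
            list(message = reason, call = NULL))
}

# Tracking wrapper around the group objective. Counts every evaluation
# (including finite-difference probes), records the history, keeps the
# best point seen, and raises a calibfe_stop condition on normal
# termination or evaluation exhaustion. Query points are projected onto
# the feasible box first: the material-parameter objectives are only
# defined for positive parameters, and some backends' internal
# finite-difference probes can step marginally outside the bounds.
make_tracker <- function(fn, scalarise, options, n_params,
                         lower = NULL, upper = NULL,
                         max_evaluations = Inf) {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  env$history <- list()
  env$best_value <- Inf
  env$best_params <- NULL
  env$best_raw <- NULL
  env$queried <- list()
  eval_fn <- function(x) {
    if (env$count >= max_evaluations) {
      stop(stop_condition("max_iterations"))
    }
    if (!is.null(lower)) x <- pmax(x, lower)
    if (!is.null(upper)) x <- pmin(x, upper)
    raw <- fn(x)
    sc <- scalarise(raw)
    env$count <- env$count + 1L
    env$queried[[env$count]] <- x
    if (options$history) {
      env$history[[env$count]] <- c(x, sc)
    }
    if (is.finite(sc) && sc < env$best_value) {
      env$best_value <- sc
      env$best_params <- x
      env$best_raw <- raw
    }
    if (!is.null(options$f_tol) && is.finite(sc) && sc < options$f_tol) {
      stop(stop_condition("objective_tol"))
    }
    raw
  }
  list(fn = eval_fn, env = env)
}

#' Forward-difference Jacobian or gradient
#'
#' Numerically differentiates a residual vector (functional) or scalar
#' objective by forward differences with step `fd_step`; when a
#' parameter sits at (or within a step of) its upper bound the probe
#' switches to a backward difference so no query leaves the feasible box.
#'
#' @param objective function of the parameter vector returning a numeric
#'   vector (residuals) or scalar.
#' @param params evaluation point.
#' @param fd_step finite-difference step, relative to the parameter
#'   magnitude (with a floor of 1), so parameters of very different
#'   scales are probed proportionately.
#' @param lower,upper optional bounds respected by the probes.
#' @return an m x p matrix (m = 1 for scalar objectives). Columns whose
#'   probe failed (non-finite objective) are `NA` with attribute
#'   `"unusable"` listing them.
#' @export
numerical_jacobian <- function(objective, params, fd_step = 1e-6,
                               lower = NULL, upper = NULL) {
  params <- as.numeric(params)
  p <- length(params)
  f0 <- as.numeric(objective(params))
  if (anyNA(f0) || any(!is.finite(f0))) {
    stop("objective is not finite at the evaluation point")
  }
  J <- matrix(NA_real_, length(f0), p)
  unusable <- integer(0)
  for (i in seq_len(p)) {
    h <- fd_step * max(1, abs(params[i]))
    xi <- params
    at_upper <- !is.null(upper) && params[i] + h > upper[i]
    if (at_upper) h <- -h
    if (!is.null(lower) && params[i] + h < lower[i]) {
      stop(sprintf("parameter %d: bounds tighter than the finite-difference step", i))
    }
    xi[i] <- params[i] + h
    h <- xi[i] - params[i]  # actual represented step
    fi <- as.numeric(objective(xi))
    if (anyNA(fi) || any(!is.finite(fi))) {
      unusable <- c(unusable, i)
    } else {
      J[, i] <- (fi - f0) / h
    }
  }
  if (length(unusable)) attr(J, "unusable") <- unusable
  J
}

# finite-difference Hessian of a scalar objective: forward differences of
# the forward-difference gradient, then symmetrised
numerical_hessian <- function(objective, params, fd_step = 1e-5,
                              lower = NULL, upper = NULL) {
  p <- length(params)
  grad_at <- function(x) {
    numerical_jacobian(objective, x, fd_step = fd_step,
                       lower = lower, upper = upper)[1, ]
  }
  g0 <- grad_at(params)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    h <- fd_step * max(1, abs(params[i]))
    xi <- params
    if (!is.null(upper) && params[i] + h > upper[i]) h <- -h
    xi[i] <- params[i] + h
    h <- xi[i] - params[i]
    H[, i] <- (grad_at(xi) - g0) / h
  }
  (H + t(H)) / 2
}
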