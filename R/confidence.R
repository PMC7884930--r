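#' Confidence intervals from the final Jacobian/Hessian and residuals
#'
#' Combines the curvature estimate at the optimum with the residuals to
#' form the parameter covariance of nonlinear least squares: the residual
#' variance is \eqn{s^2 = SSR/(n - p)} and the covariance is
#' \eqn{s^2 (J^T J)^{-1}} for functional (vector-residual) problems or
#' \eqn{2 s^2 H^{-1}} for scalar objectives, with \eqn{H} the objective
#' Hessian. Intervals use the Student-t quantile with \eqn{n - p} degrees
#' of freedom. A perfect fit (zero residuals) yields zero-width intervals.
#'
#' @param result an `optimisation_result` with Jacobian or Hessian
#'   estimates and final residuals.
#' @param n_observations total number of observations; defaults to the
#'   number of final residuals. Must exceed the parameter count.
#' @param level confidence level (default 0.95).
#' @return a `confidence_report` with `covariance`, `intervals` (one row
#'   per parameter: estimate, low, high), `residual_variance`, `level`.
#' @export
confidence_intervals <- function(result, n_observations = NULL, level = 0.95) {
  stopifnot(inherits(result, "optimisation_result"))
  p <- length(result$final_params)
  if (is.null(n_observations)) n_observations <- length(result$residuals)
  n <- n_observations
  if (n <= p) stop("confidence intervals need more observations than parameters")
  if (level <= 0 || level >= 1) stop("confidence level must lie in (0, 1)")
  ssr <- sum(result$residuals^2)
  s2 <- ssr / (n - p)

  if (result$objective_kind == "functional" ||
      (!is.null(result$jacobian) && nrow(result$jacobian) > 1L)) {
    J <- result$jacobian
    if (is.null(J) || anyNA(J)) stop("no usable Jacobian estimate in the result")
    JtJ <- crossprod(J)
    check_identifiable(JtJ, result$parameter_names)
    covariance <- s2 * solve(JtJ)
  } else {
    H <- result$hessian
    if (is.null(H) || anyNA(H)) stop("no usable Hessian estimate in the result")
    check_identifiable(H, result$parameter_names)
    covariance <- 2 * s2 * solve(H)
  }
  covariance <- (covariance + t(covariance)) / 2
  se <- sqrt(pmax(diag(covariance), 0))
  tq <- stats::qt((1 + level) / 2, df = n - p)
  est <- result$final_params
  intervals <- data.frame(parameter = result$parameter_names,
                          estimate = as.numeric(est),
                          low = as.numeric(est - tq * se),
                          high = as.numeric(est + tq * se),
                          row.names = NULL)
  structure(list(covariance = covariance, intervals = intervals,
                 residual_variance = s2, level = level,
                 n_observations = n),
            class = "confidence_report")
}

# error on a numerically singular curvature matrix, naming the
# unidentifiable parameter combination (the null-space direction)
check_identifiable <- function(M, names) {
  eig <- eigen(M, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-12
  if (min(eig$values) <= tol) {
    v <- eig$vectors[, which.min(eig$values)]
    combo <- paste(sprintf("%+.3f*%s", v, names), collapse = " ")
    stop(sprintf("singular curvature: parameter combination %s is unidentifiable",
                 combo))
  }
  invisible(TRUE)
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence report: %.0f%% intervals, s^2 = %.4g>\n",
              100 * x$level, x$residual_variance))
  print(x$intervals)
  invisible(x)
}
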