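# concatenated residuals at a parameter vector, independent of the
# aggregation mode; used for final diagnostics and confidence intervals
collect_residuals <- function(params, pairs, spec) {
  nm <- vapply(pairs, function(p) p$obs$name, character(1))
  pairs <- pairs[order(nm)]
  out <- list()
  for (p in pairs) {
    fo <- run_forward(p$model, params)
    if (!fo$failed) out[[p$obs$name]] <- compare(fo, p$obs, spec)
  }
  unlist(out, use.names = FALSE)
}

#' Minimise the group objective
#'
#' The optimisation manager: builds the tracked group objective over the
#' model/observation pairs, dispatches the method for the problem shape
#' (or an explicit `method` override such as `"newton"`), runs it, and
#' assembles the result with counts, termination reason, history, final
#' Jacobian/Hessian estimates and final residuals.
#'
#' Every objective evaluation -- including finite-difference probes -- is
#' counted in `n_evaluations` and, when `options$history` is on, recorded
#' as one history row (the initial point is row 0). If `options$f_tol` is
#' set, the run stops with termination `"objective_tol"` ("normal
#' termination") as soon as the scalar objective falls below it. An
#' all-models-failed evaluation returns a large finite penalty
#' (\eqn{10^6 \times}{1e6 x} the last successful objective value, or
#' \eqn{10^6}{1e6} before any success) so gradient-based methods retreat
#' rather than crash.
#'
#' @param pairs list of `list(model = , obs = )` pairs (see
#'   [load_pairs()]).
#' @param spec an [objective_spec()].
#' @param params a [parameter_set()].
#' @param options an [optimiser_options()].
#' @param method optional explicit method identifier overriding
#'   [select_method()] (e.g. `"newton"` for the comparison harness).
#' @return an `optimisation_result`.
#' @export
minimise <- function(pairs, spec, params, options = optimiser_options(),
                     method = NULL) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(options, "optimiser_options"),
            inherits(spec, "objective_spec"))
  objective_kind <- if (spec$comparison == "least_squares") "functional" else "scalar"
  if (is.null(method)) {
    method <- select_method(params$n, objective_kind, params$bounded)
  }
  p <- params$n

  penalty_env <- new.env(parent = emptyenv())
  penalty_env$last_good <- NULL
  raw_fn <- function(x) {
    pen <- if (is.null(penalty_env$last_good)) 1e6 else 1e6 * penalty_env$last_good
    val <- evaluate_group(x, pairs, spec, penalty = pen)
    if (!val$all_failed) penalty_env$last_good <- val$scalar_value
    if (objective_kind == "functional") val$residuals else val$scalar_value
  }
  scalarise <- if (objective_kind == "functional") {
    function(r) sqrt(mean(r^2))
  } else {
    identity
  }
  tracker <- make_tracker(raw_fn, scalarise, options, p,
                          lower = params$lower, upper = params$upper)
  fn <- tracker$fn

  run <- tryCatch(
    run_method(method, fn, params, options, objective_kind),
    calibfe_stop = function(c) list(termination = conditionMessage(c),
                                    message = "normal termination on the objective criterion",
                                    n_iterations = NA_integer_),
    error = function(e) list(termination = "failure",
                             message = conditionMessage(e),
                             n_iterations = NA_integer_)
  )

  env <- tracker$env
  if (is.null(env$best_params)) {
    stop(sprintf("optimisation failed before any successful evaluation: %s",
                 run$message %||% "unknown"))
  }
  final <- env$best_params
  names(final) <- params$names
  n_iter <- run$n_iterations
  if (is.na(n_iter)) n_iter <- env$count  # early stop: evaluations stand in

  # final diagnostics (outside the evaluation count)
  residuals <- collect_residuals(final, pairs, spec)
  scalar_obj <- function(x) {
    v <- raw_fn(x)
    if (objective_kind == "functional") sqrt(mean(v^2)) else v
  }
  jac <- hess <- NULL
  diag_try <- tryCatch({
    if (objective_kind == "functional") {
      jac <- numerical_jacobian(raw_fn, final, fd_step = options$fd_step,
                                lower = params$lower, upper = params$upper)
      hess <- 2 * crossprod(jac)  # Gauss-Newton Hessian of the SSR
    } else {
      jac <- numerical_jacobian(scalar_obj, final, fd_step = options$fd_step,
                                lower = params$lower, upper = params$upper)
      hess <- numerical_hessian(scalar_obj, final,
                                fd_step = max(options$fd_step, 1e-5),
                                lower = params$lower, upper = params$upper)
    }
    TRUE
  }, error = function(e) FALSE)

  history <- NULL
  if (options$history && length(env$history)) {
    mat <- do.call(rbind, env$history)
    history <- as.data.frame(mat)
    names(history) <- c(params$names, "objective")
    history <- cbind(iter = seq_len(nrow(history)) - 1L, history)
  }

  structure(list(final_params = final,
                 objective_value = env$best_value,
                 objective_kind = objective_kind,
                 method = method,
                 n_iterations = as.integer(n_iter),
                 n_evaluations = env$count,
                 termination = run$termination,
                 message = run$message %||% "",
                 jacobian = jac, hessian = hess,
                 residuals = residuals,
                 history = history,
                 parameter_names = params$names,
                 lower = params$lower, upper = params$upper),
            class = "optimisation_result")
}

#' @export
print.optimisation_result <- function(x, ...) {
  cat(sprintf("<optimisation result: %s>\n", x$method))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", x$parameter_names, x$final_params),
            collapse = ", "), "\n")
  cat(sprintf("  objective %.6g after %d iterations / %d evaluations (%s)\n",
              x$objective_value, x$n_iterations, x$n_evaluations,
              x$termination))
  invisible(x)
}

# dispatch table of backend runners; each returns list(termination,
# message, n_iterations)
run_method <- function(method, fn, params, options, objective_kind) {
  switch(method,
    "brent" = run_brent(fn, params, options),
    "l-bfgs-b" = run_optim(fn, params, options, "L-BFGS-B"),
    "conjugate-gradient" = run_optim(fn, params, options, "CG"),
    "trust-region-reflective" = run_nlslm(fn, params, options, bounded = TRUE),
    "levenberg-marquardt" = run_nlslm(fn, params, options, bounded = FALSE),
    "newton" = run_newton(fn, params, options),
    stop(sprintf("unknown optimisation method '%s'", method)))
}

run_brent <- function(fn, params, options) {
  if (params$n != 1L) stop("Brent's method is univariate")
  if (!is.null(params$lower) && !is.null(params$upper)) {
    interval <- c(params$lower, params$upper)
  } else if (!is.null(params$initial)) {
    x0 <- params$initial
    span <- max(abs(x0), 1)
    interval <- c(x0 - 100 * span, x0 + 100 * span)
    if (!is.null(params$lower)) interval[1] <- max(interval[1], params$lower)
    if (!is.null(params$upper)) interval[2] <- min(interval[2], params$upper)
  } else {
    stop("univariate optimisation needs bounds or an initial value")
  }
  res <- stats::optimize(function(x) fn(x), interval = interval,
                         tol = options$x_tol)
  list(termination = "parameter_tol",
       message = sprintf("interval narrowed below x_tol = %g", options$x_tol),
       n_iterations = NA_integer_)
}

run_optim <- function(fn, params, options, method) {
  if (is.null(params$initial)) stop("multivariate optimisation needs initial values")
  gr <- function(x) {
    numerical_jacobian(fn, x, fd_step = options$fd_step,
                       lower = params$lower, upper = params$upper)[1, ]
  }
  ctrl <- list(maxit = options$max_iterations,
               parscale = pmax(abs(params$initial), 1e-8))
  args <- list(par = params$initial, fn = function(x) fn(x), gr = gr,
               method = method, control = ctrl)
  if (method == "L-BFGS-B") {
    ctrl$pgtol <- options$g_tol
    args$control <- ctrl
    if (!is.null(params$lower)) args$lower <- params$lower
    if (!is.null(params$upper)) args$upper <- params$upper
  } else {
    ctrl$reltol <- options$x_tol
    args$control <- ctrl
  }
  res <- do.call(stats::optim, args)
  term <- if (res$convergence == 0L) {
    if (method == "L-BFGS-B" && grepl("PROJ", res$message %||% "", fixed = TRUE)) {
      "gradient_tol"
    } else {
      "objective_tol"
    }
  } else if (res$convergence == 1L) {
    "max_iterations"
  } else {
    "failure"
  }
  list(termination = term, message = res$message %||% "",
       n_iterations = unname(res$counts["gradient"]))
}

run_nlslm <- function(fn, params, options, bounded) {
  if (is.null(params$initial)) stop("least-squares optimisation needs initial values")
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(options$max_iterations, 1024L),
                                     ftol = options$x_tol,
                                     ptol = options$x_tol,
                                     gtol = options$g_tol,
                                     epsfcn = options$fd_step^2)
  args <- list(par = params$initial, fn = function(x) fn(x), control = ctrl)
  if (bounded) {
    args$lower <- params$lower %||% rep(-Inf, params$n)
    args$upper <- params$upper %||% rep(Inf, params$n)
  }
  res <- do.call(minpack.lm::nls.lm, args)
  term <- switch(as.character(res$info),
    "1" = "objective_tol", "2" = "parameter_tol", "3" = "objective_tol",
    "4" = "gradient_tol", "5" = "max_iterations", "6" = "objective_tol",
    "7" = "parameter_tol", "8" = "gradient_tol", "failure")
  list(termination = term, message = res$message,
       n_iterations = res$niter)
}

# damped Newton with finite-difference derivatives; kept outside the
# dispatch table as an explicit-name extra for method comparisons
run_newton <- function(fn, params, options) {
  if (is.null(params$initial)) stop("Newton's method needs initial values")
  x <- params$initial
  clip <- function(x) {
    if (!is.null(params$lower)) x <- pmax(x, params$lower)
    if (!is.null(params$upper)) x <- pmin(x, params$upper)
    x
  }
  f_old <- fn(x)
  for (it in seq_len(options$max_iterations)) {
    g <- numerical_jacobian(fn, x, fd_step = options$fd_step,
                            lower = params$lower, upper = params$upper)[1, ]
    if (sqrt(sum(g^2)) < options$g_tol) {
      return(list(termination = "gradient_tol",
                  message = "gradient norm below g_tol", n_iterations = it))
    }
    H <- numerical_hessian(fn, x, fd_step = max(options$fd_step, 1e-5),
                           lower = params$lower, upper = params$upper)
    step <- tryCatch(-solve(H, g), error = function(e) -g)
    if (sum(step * g) > 0) step <- -g  # fall back to steepest descent
    alpha <- 1
    repeat {  # backtracking keeps the iterate inside bounds and descending
      x_new <- clip(x + alpha * step)
      f_new <- fn(x_new)
      if (is.finite(f_new) && f_new <= f_old || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    if (sqrt(sum((x_new - x)^2)) < options$x_tol) {
      return(list(termination = "parameter_tol",
                  message = "step norm below x_tol", n_iterations = it))
    }
    x <- x_new
    f_old <- f_new
  }
  list(termination = "max_iterations", message = "iteration cap reached",
       n_iterations = options$max_iterations)
}
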