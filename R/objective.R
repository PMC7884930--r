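#' Experimental observation for one specimen
#'
#' @param name specimen identifier; must match the basename of the paired
#'   forward-model file.
#' @param payload scalar, numeric vector, or [curve_data()] object.
#' @return an `observation` object with fields `name`, `kind`, `payload`.
#' @export
observation <- function(name, payload) {
  kind <- if (is_curve(payload)) "curve" else if (length(payload) == 1L) "scalar" else "list"
  if (kind != "curve") {
    payload <- as.numeric(payload)
    if (anyNA(payload)) stop(sprintf("observation '%s' contains missing values", name))
  }
  structure(list(name = name, kind = kind, payload = payload),
            class = "observation")
}

#' Objective comparison specification
#'
#' Controls how model outputs are compared to observations and how
#' per-specimen residuals are aggregated across a group:
#' \itemize{
#'   \item `comparison`: `"direct"` (scalar objective built from residual
#'     RMS) or `"least_squares"` (vector residuals handed to a
#'     least-squares optimiser).
#'   \item `error_form`: `"difference"` (model minus experiment) or
#'     `"relative"` (difference divided by a normalisation reference).
#'   \item `aggregation`: `"rms_over_models"` (scalar: root of the mean
#'     over contributing specimens of each specimen's mean-squared
#'     residual) or `"concatenated_residuals"` (all contributing residual
#'     vectors stacked in filename-sorted order).
#'   \item `normalisation_reference`: in relative mode, divide by the
#'     per-point experimental value (`"experimental_value"`) or by the
#'     specimen's maximum absolute experimental value
#'     (`"max_experimental"`).
#' }
#'
#' @param comparison,error_form,aggregation,normalisation_reference see
#'   above.
#' @return an `objective_spec` object.
#' @export
objective_spec <- function(comparison = c("direct", "least_squares"),
                           error_form = c("difference", "relative"),
                           aggregation = c("rms_over_models", "concatenated_residuals"),
                           normalisation_reference = c("experimental_value", "max_experimental")) {
  comparison <- match.arg(comparison)
  error_form <- match.arg(error_form)
  aggregation <- match.arg(aggregation)
  normalisation_reference <- match.arg(normalisation_reference)
  if (comparison == "direct" && aggregation == "concatenated_residuals") {
    stop("concatenated residuals are only valid for least-squares (functional) objectives")
  }
  if (comparison == "least_squares" && aggregation == "rms_over_models") {
    stop("rms_over_models is only valid for direct (scalar) objectives")
  }
  structure(list(comparison = comparison, error_form = error_form,
                 aggregation = aggregation,
                 normalisation_reference = normalisation_reference),
            class = "objective_spec")
}

#' Residuals between one model output and its observation
#'
#' Scalar outputs give a length-1 residual; lists give elementwise
#' residuals; curves are first interpolated onto the common grid of the
#' denser curve within the x-overlap. In relative mode each residual is
#' divided by the chosen normalisation reference; a zero reference is an
#' error naming the offending point.
#'
#' @param model_out a non-failed [forward_output()].
#' @param obs an [observation()] of matching kind.
#' @param spec an [objective_spec()].
#' @return numeric residual vector.
#' @export
compare <- function(model_out, obs, spec) {
  stopifnot(is_forward_output(model_out), inherits(obs, "observation"),
            inherits(spec, "objective_spec"))
  if (model_out$failed) stop("cannot compare a failed model output; filter failures first")
  if (model_out$kind != obs$kind) {
    stop(sprintf("specimen '%s': model output kind '%s' does not match observation kind '%s'",
                 obs$name, model_out$kind, obs$kind))
  }
  if (obs$kind == "curve") {
    common <- interpolate_to_common_grid(model_out$value, obs$payload, name = obs$name)
    y_mod <- common$y_model
    y_exp <- common$y_exp
  } else {
    y_mod <- model_out$value
    y_exp <- obs$payload
    if (length(y_mod) != length(y_exp)) {
      stop(sprintf("specimen '%s': model output length %d does not match observation length %d",
                   obs$name, length(y_mod), length(y_exp)))
    }
  }
  res <- y_mod - y_exp
  if (spec$error_form == "relative") {
    ref <- switch(spec$normalisation_reference,
                  experimental_value = y_exp,
                  max_experimental = rep(max(abs(y_exp)), length(y_exp)))
    zero <- which(ref == 0)
    if (length(zero)) {
      stop(sprintf("specimen '%s': zero normalisation reference at point %d in relative mode",
                   obs$name, zero[1]))
    }
    res <- res / ref
  }
  res
}

#' Evaluate the group objective at a parameter vector
#'
#' Runs every forward model at `params` and aggregates residuals over the
#' converged subset. Solver failure is data, not an exception: failed
#' models are counted in `n_failed` and excluded; only if every model
#' fails is the configured penalty returned, so gradient-based optimisers
#' retreat rather than crash.
#'
#' @param params numeric parameter vector shared by all models.
#' @param pairs list of `list(model = forward_model, obs = observation)`.
#' @param spec an [objective_spec()].
#' @param penalty scalar objective value (or per-residual magnitude)
#'   substituted when all models fail.
#' @return an `objective_value` with fields `scalar_value`, `residuals`
#'   (least-squares mode), `n_contributing`, `n_failed`, and
#'   `per_model_rms`.
#' @export
evaluate_group <- function(params, pairs, spec, penalty = 1e6) {
  stopifnot(length(pairs) >= 1L, inherits(spec, "objective_spec"))
  # deterministic filename-sorted order regardless of input order
  nm <- vapply(pairs, function(p) p$obs$name, character(1))
  pairs <- pairs[order(nm)]
  res_list <- list()
  n_failed <- 0L
  for (p in pairs) {
    out <- run_forward(p$model, params)
    if (out$failed) {
      n_failed <- n_failed + 1L
    } else {
      res_list[[p$obs$name]] <- compare(out, p$obs, spec)
    }
  }
  n_contributing <- length(res_list)
  if (n_contributing == 0L) {
    if (spec$comparison == "least_squares") {
      n_total <- sum(vapply(pairs, function(p) observation_length(p$obs), numeric(1)))
      val <- structure(list(scalar_value = penalty,
                            residuals = rep(penalty, n_total),
                            n_contributing = 0L, n_failed = n_failed,
                            per_model_rms = numeric(0), all_failed = TRUE),
                       class = "objective_value")
    } else {
      val <- structure(list(scalar_value = penalty, residuals = NULL,
                            n_contributing = 0L, n_failed = n_failed,
                            per_model_rms = numeric(0), all_failed = TRUE),
                       class = "objective_value")
    }
    return(val)
  }
  per_model_rms <- vapply(res_list, function(r) sqrt(mean(r^2)), numeric(1))
  if (spec$aggregation == "rms_over_models") {
    msq <- vapply(res_list, function(r) mean(r^2), numeric(1))
    scalar_value <- sqrt(mean(msq))
    residuals <- NULL
  } else {
    residuals <- unlist(res_list, use.names = FALSE)
    scalar_value <- sqrt(mean(residuals^2))
  }
  structure(list(scalar_value = scalar_value, residuals = residuals,
                 n_contributing = n_contributing, n_failed = n_failed,
                 per_model_rms = per_model_rms, all_failed = FALSE),
            class = "objective_value")
}

observation_length <- function(obs) {
  if (obs$kind == "curve") length(obs$payload$x) else length(obs$payload)
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("<objective: %.6g (%d contributing, %d failed)>\n",
              x$scalar_value, x$n_contributing, x$n_failed))
  invisible(x)
}
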