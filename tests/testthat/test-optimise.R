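test_that("method dispatch reproduces every cell of the dispatch table", {
  expect_identical(select_method(1, "scalar", bounded = TRUE), "brent")
  expect_identical(select_method(1, "scalar", bounded = FALSE), "brent")
  expect_identical(select_method(2, "scalar", bounded = TRUE), "l-bfgs-b")
  expect_identical(select_method(3, "scalar", bounded = FALSE), "conjugate-gradient")
  expect_identical(select_method(2, "functional", bounded = TRUE), "trust-region-reflective")
  expect_identical(select_method(3, "functional", bounded = FALSE), "levenberg-marquardt")
  expect_error(select_method(1, "functional", bounded = TRUE), "univariate functional")
})

test_that("Brent finds the analytic minimum of a quadratic scalar objective", {
  pair <- list(model = forward_model("custom", function(p) forward_output(p[1]),
                                     n_params = 1, output_kind = "scalar"),
               obs = observation("q", 3))
  res <- minimise(list(pair), direct_diff_spec(),
                  parameter_set("x", lower = 0, upper = 10),
                  optimiser_options(x_tol = 1e-10))
  expect_identical(res$method, "brent")
  expect_equal(unname(res$final_params), 3, tolerance = 1e-7)
  expect_lt(res$objective_value, 1e-7)
})

test_that("Levenberg-Marquardt solves a consistent linear residual system exactly", {
  A <- rbind(c(1, 0), c(0, 1), c(1, 1))
  pair <- list(model = linear_model(A), obs = observation("lin", c(1, 2, 3)))
  res <- minimise(list(pair), ls_diff_spec(),
                  parameter_set(c("a", "b"), initial = c(5, -4)),
                  optimiser_options())
  expect_identical(res$method, "levenberg-marquardt")
  expect_equal(unname(res$final_params), c(1, 2), tolerance = 1e-8)
  expect_lt(res$objective_value, 1e-10)
  # matches the normal-equations solution on an overdetermined system
  set.seed(1)
  A2 <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  pair2 <- list(model = linear_model(A2), obs = observation("lin2", y))
  res2 <- minimise(list(pair2), ls_diff_spec(),
                   parameter_set(c("a", "b"), initial = c(0.5, 0.5)),
                   optimiser_options())
  expect_equal(unname(res2$final_params),
               as.numeric(solve(crossprod(A2), crossprod(A2, y))),
               tolerance = 1e-8)
})

test_that("numerical Jacobian matches analytic derivatives", {
  expect_equal(numerical_jacobian(function(x) 2 * x, 1, 1e-6),
               matrix(2), tolerance = 1e-5)
  expect_equal(numerical_jacobian(function(x) x[1] * x[2], c(2, 3), 1e-6),
               matrix(c(3, 2), 1), tolerance = 1e-5)
  expect_equal(numerical_jacobian(function(x) c(1, 2), c(5, 6), 1e-6),
               matrix(0, 2, 2))
  # probes switch to backward difference at an active upper bound
  seen <- list()
  f <- function(x) { seen[[length(seen) + 1]] <<- x; x[1]^2 }
  J <- numerical_jacobian(f, 4, 1e-6, lower = 0, upper = 4)
  expect_equal(J[1, 1], 8, tolerance = 1e-4)
  expect_true(all(vapply(seen, function(x) x <= 4, logical(1))))
})

test_that("all queried points respect declared bounds", {
  queried <- list()
  spy <- forward_model("custom", function(p) {
    queried[[length(queried) + 1]] <<- p
    forward_output(c(p[1] - 1.5, p[2] - 2.5, p[1] + p[2] - 4), "list")
  }, n_params = 2, output_kind = "list")
  pair <- list(model = spy, obs = observation("spy", c(0, 0, 0)))
  lower <- c(1, 1); upper <- c(3, 3)
  res <- minimise(list(pair), ls_diff_spec(),
                  parameter_set(c("a", "b"), initial = c(2.8, 1.2),
                                lower = lower, upper = upper),
                  optimiser_options())
  expect_true(all(vapply(queried, function(p) {
    all(p >= lower - 1e-12) && all(p <= upper + 1e-12)
  }, logical(1))))
  expect_equal(unname(res$final_params), c(1.5, 2.5), tolerance = 1e-6)

  # scalar path (L-BFGS-B) under the same scrutiny
  queried <- list()
  spy2 <- forward_model("custom", function(p) {
    queried[[length(queried) + 1]] <<- p
    forward_output((p[1] - 2)^2 + (p[2] - 2)^2 + 1)
  }, n_params = 2, output_kind = "scalar")
  pair2 <- list(model = spy2, obs = observation("spy2", 1))
  res2 <- minimise(list(pair2), direct_diff_spec(),
                   parameter_set(c("a", "b"), initial = c(1.2, 2.9),
                                 lower = lower, upper = upper),
                   optimiser_options())
  expect_identical(res2$method, "l-bfgs-b")
  expect_true(all(vapply(queried, function(p) {
    all(p >= lower - 1e-12) && all(p <= upper + 1e-12)
  }, logical(1))))
})

test_that("evaluation counts, history and best-so-far diagnostics are coherent", {
  pair <- list(model = forward_model("custom", function(p) forward_output(p[1]),
                                     n_params = 1, output_kind = "scalar"),
               obs = observation("q", 3))
  res <- minimise(list(pair), direct_diff_spec(),
                  parameter_set("x", lower = 0, upper = 10),
                  optimiser_options())
  expect_gte(res$n_evaluations, res$n_iterations)
  expect_equal(nrow(res$history), res$n_evaluations)
  expect_identical(res$history$iter[1], 0L)
  # running minimum of the recorded objective is non-increasing
  best <- cummin(res$history$objective)
  expect_true(all(diff(best) <= 0))
  # final objective re-checks against a fresh group evaluation
  expect_equal(res$objective_value,
               evaluate_group(res$final_params, list(pair),
                              direct_diff_spec())$scalar_value,
               tolerance = 1e-12)
})

test_that("normal termination fires when the objective falls below f_tol", {
  pair <- list(model = forward_model("custom", function(p) forward_output(p[1]),
                                     n_params = 1, output_kind = "scalar"),
               obs = observation("q", 3))
  res <- minimise(list(pair), direct_diff_spec(),
                  parameter_set("x", lower = 0, upper = 10),
                  optimiser_options(f_tol = 0.5))
  expect_identical(res$termination, "objective_tol")
  expect_lt(res$objective_value, 0.5)
})

test_that("an objective that raises aborts with a captured failure", {
  boom <- forward_model("custom", function(p) stop("mesh exploded"),
                        n_params = 1, output_kind = "scalar")
  pair <- list(model = boom, obs = observation("b", 1))
  expect_error(minimise(list(pair), direct_diff_spec(),
                        parameter_set("x", lower = 0, upper = 1),
                        optimiser_options()),
               "mesh exploded")
})

test_that("Newton's comparison method solves the quadratic from an explicit override", {
  pair <- list(model = forward_model("custom", function(p) forward_output((p[1] - 3)^2 + 2),
                                     n_params = 1, output_kind = "scalar"),
               obs = observation("q", 2))
  res <- minimise(list(pair), direct_diff_spec(),
                  parameter_set("x", initial = 1, lower = 0, upper = 10),
                  optimiser_options(x_tol = 1e-9), method = "newton")
  expect_identical(res$method, "newton")
  expect_equal(unname(res$final_params), 3, tolerance = 1e-4)
  # newton is never returned by the dispatch table
  expect_false("newton" %in% c(select_method(1, "scalar"),
                               select_method(2, "scalar", TRUE),
                               select_method(2, "scalar", FALSE),
                               select_method(2, "functional", TRUE),
                               select_method(2, "functional", FALSE)))
})

test_that("group calibration survives specimens that fail at some parameter values", {
  # one model fails for p > 2, the other everywhere converges; the
  # optimiser must still find the shared minimum at p = 1
  flaky <- forward_model("custom", function(p) {
    if (p[1] > 2) forward_failure("scalar") else forward_output(p[1])
  }, n_params = 1, output_kind = "scalar")
  solid <- forward_model("custom", function(p) forward_output(2 * p[1]),
                         n_params = 1, output_kind = "scalar")
  pairs <- list(list(model = flaky, obs = observation("flaky", 1)),
                list(model = solid, obs = observation("solid", 2)))
  res <- minimise(pairs, direct_diff_spec(),
                  parameter_set("p", lower = 0.1, upper = 10),
                  optimiser_options())
  expect_equal(unname(res$final_params), 1, tolerance = 1e-5)
})

test_that("history files have a header, one row per evaluation, and overwrite on rerun", {
  pair <- list(model = forward_model("custom", function(p) forward_output(p[1]),
                                     n_params = 1, output_kind = "scalar"),
               obs = observation("q", 3))
  res <- minimise(list(pair), direct_diff_spec(),
                  parameter_set("x", lower = 0, upper = 10),
                  optimiser_options())
  path <- tempfile(fileext = ".txt")
  write_history(res, path)
  lines <- readLines(path)
  expect_identical(lines[1], "iter\tx\tobjective")
  expect_length(lines, res$n_evaluations + 1L)
  back <- read_history(path)
  expect_equal(back$objective, res$history$objective, tolerance = 1e-12)
  # overwrite, never append
  write_history(res, path)
  expect_length(readLines(path), res$n_evaluations + 1L)
  # disabled history records nothing
  res2 <- minimise(list(pair), direct_diff_spec(),
                   parameter_set("x", lower = 0, upper = 10),
                   optimiser_options(history = FALSE))
  expect_null(res2$history)
  expect_error(write_history(res2, tempfile()), "history")
})

test_that("conjugate gradient handles the unbounded multivariate scalar cell", {
  pair <- list(model = forward_model("custom", function(p)
                 forward_output((p[1] - 1)^2 + (p[2] + 2)^2 + 5),
               n_params = 2, output_kind = "scalar"),
               obs = observation("cg", 5))
  res <- minimise(list(pair), direct_diff_spec(),
                  parameter_set(c("a", "b"), initial = c(4, 4)),
                  optimiser_options())
  expect_identical(res$method, "conjugate-gradient")
  expect_equal(unname(res$final_params), c(1, -2), tolerance = 1e-3)
})
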