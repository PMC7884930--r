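# shared builders for toy models and pairs

# custom model returning a fixed payload regardless of parameters
constant_model <- function(payload, name = "const", n_params = 1L) {
  kind <- if (inherits(payload, "calib_curve")) "curve" else if (length(payload) == 1L) "scalar" else "list"
  forward_model("custom", function(params) forward_output(payload, kind),
                name = name, n_params = n_params, output_kind = kind)
}

# custom model that always fails (solver "NaN" sentinel)
failing_model <- function(name = "fail", kind = "scalar", n_params = 1L) {
  forward_model("custom", function(params) forward_failure(kind),
                name = name, n_params = n_params, output_kind = kind)
}

toy_pair <- function(model_payload, obs_payload, name = "toy", n_params = 1L) {
  list(model = constant_model(model_payload, name, n_params),
       obs = observation(name, obs_payload))
}

# linear-map model: output = A %*% params (list kind)
linear_model <- function(A, name = "lin") {
  forward_model("custom", function(params) forward_output(as.numeric(A %*% params), "list"),
                name = name, n_params = ncol(A), output_kind = "list")
}

# random small greyscale chain for property loops
random_chain <- function(n = 8L) {
  greyscale_lattice(greyscales = runif(n, 0.2, 1),
                    lengths = runif(n, 0.5, 1.5),
                    areas = runif(n, 50, 150),
                    prescribed_displacement = 0.5)
}

direct_diff_spec <- function() objective_spec("direct", "difference", "rms_over_models")
ls_diff_spec <- function() objective_spec("least_squares", "difference", "concatenated_residuals")
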