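#' Forward-model contract
#'
#' A forward model binds a specimen definition (one of the three built-in
#' model kinds) to a parameter-vector-to-output map. Running a model never
#' raises on solver failure: it returns a failed [forward_output()] so
#' that group calibration can proceed over the converged subset.
#'
#' Built-in kinds and their calibrated parameters:
#' \describe{
#'   \item{`bone_greyscale`}{greyscale-to-modulus slope (1 parameter);
#'     scalar apparent-stiffness output.}
#'   \item{`osteodisc_goh`}{GOH fibre parameters k1, k2 (2 parameters);
#'     force-displacement curve output.}
#'   \item{`interface_slice`}{interface stiffnesses k_r, k_t
#'     (2 parameters); list of radial displacements.}
#' }
#'
#' In addition to the built-in kinds, `kind = "custom"` accepts any R
#' function mapping a parameter vector to a [forward_output()] (or a
#' value coercible to one), mirroring the contract that a model
#' definition is simply a function of the parameters. Custom models live
#' in memory only and cannot be serialised to model files.
#'
#' @param kind one of the built-in model kinds, or `"custom"`.
#' @param definition kind-specific specimen definition (see the
#'   constructors [greyscale_lattice()], [goh_fixed_params()],
#'   [interface_lattice()]), or for `"custom"` a function of the
#'   parameter vector.
#' @param name specimen identifier (defaults to the file basename when
#'   read from disk).
#' @param displacements for `osteodisc_goh`: the displacement grid the
#'   curve is evaluated on.
#' @param n_params,output_kind for `"custom"` models: the parameter
#'   count and the payload kind the function returns.
#' @return a `forward_model` object.
#' @export
forward_model <- function(kind, definition, name = "specimen",
                          displacements = NULL, n_params = NULL,
                          output_kind = NULL) {
  kind <- match.arg(kind, c("bone_greyscale", "osteodisc_goh",
                            "interface_slice", "custom"))
  if (kind == "custom") {
    if (!is.function(definition)) stop("custom models require a function definition")
    if (is.null(n_params) || is.null(output_kind)) {
      stop("custom models require n_params and output_kind")
    }
    output_kind <- match.arg(output_kind, c("scalar", "list", "curve"))
    return(structure(list(kind = kind, definition = definition, name = name,
                          displacements = NULL,
                          n_params = as.integer(n_params),
                          output_kind = output_kind),
                     class = "forward_model"))
  }
  expected <- switch(kind,
    bone_greyscale = "greyscale_lattice",
    osteodisc_goh = "goh_fixed_params",
    interface_slice = "interface_lattice")
  if (!inherits(definition, expected)) {
    stop(sprintf("model kind '%s' requires a %s definition", kind, expected))
  }
  if (kind == "osteodisc_goh" && is.null(displacements)) {
    stop("osteodisc_goh models need a displacement grid")
  }
  structure(list(kind = kind, definition = definition, name = name,
                 displacements = displacements),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward model '%s': %s, %d parameter(s)>\n",
              x$name, x$kind, n_model_params(x)))
  invisible(x)
}

#' Number of calibrated parameters of a model kind
#' @param model a `forward_model`.
#' @return integer.
#' @export
n_model_params <- function(model) {
  switch(model$kind, bone_greyscale = 1L, osteodisc_goh = 2L,
         interface_slice = 2L, custom = model$n_params)
}

#' Output payload kind of a model
#' @param model a `forward_model`.
#' @return `"scalar"`, `"curve"` or `"list"`.
#' @export
model_output_kind <- function(model) {
  switch(model$kind, bone_greyscale = "scalar", osteodisc_goh = "curve",
         interface_slice = "list", custom = model$output_kind)
}

#' Run a forward model at a parameter vector
#'
#' @param model a `forward_model`.
#' @param params numeric parameter vector of length [n_model_params()].
#' @return a [forward_output()]; `failed = TRUE` on solver failure.
#' @export
run_forward <- function(model, params) {
  stopifnot(inherits(model, "forward_model"))
  params <- as.numeric(params)
  if (length(params) != n_model_params(model)) {
    stop(sprintf("model '%s' expects %d parameter(s), got %d",
                 model$name, n_model_params(model), length(params)))
  }
  switch(model$kind,
    bone_greyscale = greyscale_apparent_stiffness(model$definition, params[1]),
    osteodisc_goh = goh_force_displacement(params[1], params[2],
                                           model$definition,
                                           model$displacements),
    interface_slice = interface_displacements(model$definition,
                                              params[1], params[2]),
    custom = {
      out <- model$definition(params)
      if (!is_forward_output(out)) out <- forward_output(out, model$output_kind)
      out
    })
}

#' Read a forward-model definition file
#'
#' Model files are YAML with a `kind` key naming a built-in model and the
#' kind-specific construction fields (documented under the respective
#' constructors). One file per specimen; the experimental observation is
#' the same-basename `.dat` file.
#'
#' @param path path to a `.yaml` model file.
#' @return a `forward_model` named after the file basename.
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  def <- yaml::read_yaml(path)
  if (is.null(def$kind)) stop(sprintf("model file %s lacks a 'kind' key", path))
  name <- sub("\\.(ya?ml)$", "", basename(path))
  switch(def$kind,
    bone_greyscale = forward_model(
      "bone_greyscale",
      greyscale_lattice(def$greyscales, def$lengths, def$areas,
                        def$prescribed_displacement),
      name = name),
    osteodisc_goh = forward_model(
      "osteodisc_goh",
      goh_fixed_params(c10 = def$c10, kappa = def$kappa, theta = def$theta,
                       d_comp = def$d_comp %||% 0,
                       specimen_area = def$specimen_area,
                       specimen_height = def$specimen_height),
      name = name, displacements = def$displacements),
    interface_slice = forward_model(
      "interface_slice",
      interface_lattice(def$n_lamellae, def$nodes_per_lamella,
                        inner_radius = def$inner_radius,
                        lamella_spacing = def$lamella_spacing,
                        sector_deg = def$sector_deg,
                        lamella_stiffness = def$lamella_stiffness,
                        load = def$load,
                        load_angle_deg = def$load_angle_deg %||% 45,
                        tracked_points = def$tracked_points),
      name = name),
    stop(sprintf("unknown model kind '%s' in %s", def$kind, path)))
}

#' Write a forward-model definition file
#'
#' Inverse of [read_model_file()]; used by the fixture generator.
#'
#' @param model a `forward_model`.
#' @param path destination `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_model_file <- function(model, path) {
  stopifnot(inherits(model, "forward_model"))
  if (model$kind == "custom") stop("custom models are in-memory only and cannot be serialised")
  d <- model$definition
  rec <- switch(model$kind,
    bone_greyscale = list(kind = "bone_greyscale",
                          greyscales = d$greyscales, lengths = d$lengths,
                          areas = d$areas,
                          prescribed_displacement = d$prescribed_displacement),
    osteodisc_goh = list(kind = "osteodisc_goh", c10 = d$c10,
                         kappa = d$kappa, theta = d$theta,
                         d_comp = d$d_comp,
                         specimen_area = d$specimen_area,
                         specimen_height = d$specimen_height,
                         displacements = model$displacements),
    interface_slice = list(kind = "interface_slice",
                           n_lamellae = d$n_lamellae,
                           nodes_per_lamella = d$nodes_per_lamella,
                           inner_radius = d$inner_radius,
                           lamella_spacing = d$lamella_spacing,
                           sector_deg = d$sector_deg,
                           lamella_stiffness = d$lamella_stiffness,
                           load = d$load,
                           load_angle_deg = d$load_angle_deg,
                           tracked_points = d$tracked_points))
  yaml::write_yaml(rec, path, precision = 17L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
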