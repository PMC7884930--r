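#' Fibre-reinforced disc specimen (Gasser-Ogden-Holzapfel)
#'
#' Desk-scale analogue of an osteodisc compression/tension model: a
#' homogeneous incompressible uniaxial specimen obeying the GOH
#' fibre-reinforced hyperelastic law. The ground matrix is neo-Hookean
#' (coefficient c10); two symmetric fibre families at +/- theta degrees to
#' the loading axis with dispersion kappa stiffen exponentially, in
#' tension only. The two calibrated parameters are the fibre stiffness k1
#' (MPa) and the dimensionless exponent k2; the remaining constitutive
#' constants and the specimen geometry are held fixed.
#'
#' @param c10 ground-matrix coefficient (MPa), > 0.
#' @param kappa fibre dispersion in [0, 1/3] (0 = perfectly aligned,
#'   1/3 = isotropic).
#' @param theta fibre angle to the loading axis (degrees).
#' @param d_comp compressibility coefficient; retained for interface
#'   completeness but unused under the incompressible kinematics.
#' @param specimen_area reference cross-section area (mm^2), > 0.
#' @param specimen_height reference height (mm), > 0.
#' @return a `goh_fixed_params` object.
#' @export
goh_fixed_params <- function(c10 = 0.1, kappa = 0.1, theta = 30,
                             d_comp = 0, specimen_area = 200,
                             specimen_height = 10) {
  if (c10 <= 0) stop("c10 must be strictly positive")
  if (kappa < 0 || kappa > 1 / 3) stop("kappa must lie in [0, 1/3]")
  if (specimen_area <= 0 || specimen_height <= 0) {
    stop("specimen geometry must be strictly positive")
  }
  structure(list(c10 = c10, kappa = kappa, theta = theta, d_comp = d_comp,
                 specimen_area = specimen_area,
                 specimen_height = specimen_height),
            class = "goh_fixed_params")
}

# Reduced strain energy density (MPa) under incompressible uniaxial
# stretch lambda (lateral stretch lambda^(-1/2)). Fibre term uses the
# dispersed invariant E = kappa*(I1 - 3) + (1 - 3 kappa)*(I4 - 1) with a
# Macaulay bracket so fibres act in tension only; the two families at
# +/- theta share I4 under uniaxial kinematics.
goh_energy <- function(lambda, k1, k2, fixed) {
  th <- fixed$theta * pi / 180
  i1 <- lambda^2 + 2 / lambda
  i4 <- lambda^2 * cos(th)^2 + sin(th)^2 / lambda
  e <- fixed$kappa * (i1 - 3) + (1 - 3 * fixed$kappa) * (i4 - 1)
  e <- pmax(e, 0)
  fib <- if (k2 > 0) {
    k1 / (2 * k2) * expm1(k2 * e^2)
  } else {
    k1 / 2 * e^2  # continuous k2 -> 0 limit
  }
  fixed$c10 * (i1 - 3) + 2 * fib
}

# d(energy)/d(lambda); nominal axial stress (MPa) since force =
# Cauchy stress x current area = A0 * dPsi/dlambda for incompressible
# uniaxial loading.
goh_nominal_stress <- function(lambda, k1, k2, fixed) {
  th <- fixed$theta * pi / 180
  i1p <- 2 * lambda - 2 / lambda^2
  i4p <- 2 * lambda * cos(th)^2 - sin(th)^2 / lambda^2
  i1 <- lambda^2 + 2 / lambda
  i4 <- lambda^2 * cos(th)^2 + sin(th)^2 / lambda
  e <- fixed$kappa * (i1 - 3) + (1 - 3 * fixed$kappa) * (i4 - 1)
  ep <- fixed$kappa * i1p + (1 - 3 * fixed$kappa) * i4p
  active <- e > 0
  fib <- numeric(length(lambda))
  fib[active] <- k1 * e[active] * exp(k2 * e[active]^2) * ep[active]
  fixed$c10 * i1p + 2 * fib
}

#' Force-displacement response of the GOH specimen
#'
#' Evaluates the whole non-linear force-displacement curve at the given
#' axial displacements: each displacement u maps to the homogeneous
#' stretch lambda = 1 + u/h, the axial force is the Cauchy stress times
#' the current area (equivalently nominal stress times reference area).
#' The curve passes through (0, 0) and is non-decreasing in k1 pointwise.
#' Exponential overflow at extreme k2 returns a failed output.
#'
#' @param k1 fibre stiffness-like parameter (MPa), > 0.
#' @param k2 dimensionless fibre exponent, > 0.
#' @param fixed a `goh_fixed_params`.
#' @param displacements axial displacements (mm), non-negative, strictly
#'   increasing from 0.
#' @return `forward_output` of kind `"curve"` (displacement mm vs force N).
#' @export
goh_force_displacement <- function(k1, k2, fixed, displacements) {
  stopifnot(inherits(fixed, "goh_fixed_params"))
  if (!is.finite(k1) || k1 <= 0 || !is.finite(k2) || k2 <= 0) {
    stop("GOH parameters k1 and k2 must be strictly positive")
  }
  u <- as.numeric(displacements)
  if (length(u) < 2L || u[1] != 0 || any(diff(u) <= 0) || any(u < 0)) {
    stop("displacements must be non-negative and strictly increasing from 0")
  }
  lambda <- 1 + u / fixed$specimen_height
  stress <- goh_nominal_stress(lambda, k1, k2, fixed)
  force <- stress * fixed$specimen_area
  if (anyNA(force) || any(!is.finite(force))) {
    return(forward_failure("curve", "overflow in fibre exponential"))
  }
  forward_output(curve_data(u, force), "curve")
}
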