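#' Greyscale-mapped elastic chain
#'
#' Desk-scale analogue of an image-based vertebral body model: a chain of
#' uniaxial linear-elastic elements whose moduli are mapped linearly from
#' normalised CT greyscale values, loaded by a prescribed end displacement.
#' The observable is the apparent stiffness (reaction force over prescribed
#' displacement, N/mm), which is exactly linear in the mapping slope.
#'
#' @param greyscales per-element normalised greyscale values in (0, 1].
#' @param lengths element lengths (mm), strictly positive.
#' @param areas element cross-section areas (mm^2), non-negative (a zero
#'   area produces a singular system and hence a failed solve, exercising
#'   the solver-failure contract).
#' @param prescribed_displacement end displacement (mm), non-zero.
#' @return a `greyscale_lattice` object.
#' @export
greyscale_lattice <- function(greyscales, lengths, areas, prescribed_displacement) {
  greyscales <- as.numeric(greyscales)
  lengths <- as.numeric(lengths)
  areas <- as.numeric(areas)
  n <- length(greyscales)
  if (n < 1L) stop("lattice needs at least one element")
  if (length(lengths) != n || length(areas) != n) {
    stop("greyscales, lengths and areas must have equal length")
  }
  if (any(greyscales <= 0) || any(greyscales > 1)) {
    stop("greyscale values must lie in (0, 1]")
  }
  if (any(lengths <= 0)) stop("element lengths must be strictly positive")
  if (any(areas < 0)) stop("element areas must be non-negative")
  if (!is.finite(prescribed_displacement) || prescribed_displacement == 0) {
    stop("prescribed displacement must be finite and non-zero")
  }
  structure(list(greyscales = greyscales, lengths = lengths, areas = areas,
                 prescribed_displacement = as.numeric(prescribed_displacement)),
            class = "greyscale_lattice")
}

#' Apparent stiffness of a greyscale-mapped chain
#'
#' Maps each element modulus as E_i = slope * GS_i, assembles the 1D
#' linear-elastic system, solves it under the prescribed end displacement
#' with the opposite end fixed, and returns reaction force divided by
#' displacement. Singular systems (e.g. a zero-area element) return a
#' failed output rather than raising.
#'
#' @param lattice a `greyscale_lattice`.
#' @param slope modulus per unit normalised greyscale (MPa); must be > 0.
#' @return `forward_output` of kind `"scalar"` (stiffness, N/mm).
#' @export
greyscale_apparent_stiffness <- function(lattice, slope) {
  stopifnot(inherits(lattice, "greyscale_lattice"))
  if (!is.finite(slope) || slope <= 0) stop("mapping slope must be strictly positive")
  k <- slope * lattice$greyscales * lattice$areas / lattice$lengths
  n <- length(k)
  d <- lattice$prescribed_displacement
  if (n == 1L) {
    if (k[1] <= 0) return(forward_failure("scalar", "singular system"))
    return(forward_output(k[1], "scalar"))
  }
  # internal nodes 1..n-1; node 0 fixed, node n prescribed at d
  K <- matrix(0, n - 1L, n - 1L)
  for (e in seq_len(n)) {
    a <- e - 1L  # node indices of element e: e-1, e (0-based)
    b <- e
    if (a >= 1L && a <= n - 1L) K[a, a] <- K[a, a] + k[e]
    if (b >= 1L && b <= n - 1L) K[b, b] <- K[b, b] + k[e]
    if (a >= 1L && a <= n - 1L && b >= 1L && b <= n - 1L) {
      K[a, b] <- K[a, b] - k[e]
      K[b, a] <- K[b, a] - k[e]
    }
  }
  f <- numeric(n - 1L)
  f[n - 1L] <- k[n] * d
  u <- tryCatch(solve(K, f), error = function(e) NULL)
  if (is.null(u) || anyNA(u) || any(!is.finite(u))) {
    return(forward_failure("scalar", "singular system"))
  }
  reaction <- k[n] * (d - u[n - 1L])
  stiffness <- reaction / d
  if (!is.finite(stiffness) || stiffness <= 0) {
    return(forward_failure("scalar", "non-positive stiffness from degenerate system"))
  }
  forward_output(stiffness, "scalar")
}
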