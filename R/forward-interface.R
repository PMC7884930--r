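#' Spring-coupled lamellar interface lattice
#'
#' Desk-scale analogue of a 2D radial annulus slice: concentric lamellae
#' (arcs of nodes over an angular sector) carry in-plane elastic chord
#' springs, and adjacent lamellae are joined node-by-node by interface
#' springs with radial stiffness `k_r` and tangential stiffness `k_t`
#' acting in the local polar frame at each node. Because the local frame
#' rotates along the arc, both interface stiffnesses influence the radial
#' displacements observed at the interlamellar junctions. The outermost
#' lamella is fixed and a radial tension is applied to the innermost one.
#'
#' @param n_lamellae number of lamellae (>= 2).
#' @param nodes_per_lamella nodes along each lamella (>= 2).
#' @param inner_radius radius of the innermost lamella (mm).
#' @param lamella_spacing radial distance between lamellae (mm).
#' @param sector_deg angular span of the slice (degrees).
#' @param lamella_stiffness chord-spring stiffness within lamellae (N/mm);
#'   scalar or one value per lamella.
#' @param load total tension applied to the inner lamella (N), shared
#'   equally across its nodes.
#' @param load_angle_deg angle of the applied pull relative to the local
#'   radial direction at each loaded node (degrees). The default 45
#'   loads the interfaces in a mix of opening (radial) and sliding
#'   (tangential) modes, so both stiffnesses are identifiable from the
#'   radial observations; 0 is a purely radial pull.
#' @param tracked_points node indices (1-based, in lamella-major order:
#'   node j of lamella i is (i - 1) * nodes_per_lamella + j) whose radial
#'   displacement is observed.
#' @return an `interface_lattice` object carrying node coordinates, the
#'   spring list, boundary conditions and tracked points.
#' @export
interface_lattice <- function(n_lamellae, nodes_per_lamella,
                              inner_radius = 5, lamella_spacing = 0.5,
                              sector_deg = 60, lamella_stiffness = 50,
                              load = 1, load_angle_deg = 45,
                              tracked_points = NULL) {
  if (n_lamellae < 2L) stop("lattice needs at least 2 lamellae")
  if (nodes_per_lamella < 1L) stop("each lamella needs at least 1 node")
  if (inner_radius <= 0 || lamella_spacing <= 0) stop("geometry must be strictly positive")
  ks <- rep_len(as.numeric(lamella_stiffness), n_lamellae)
  if (any(ks < 0)) stop("lamella stiffness must be non-negative")
  m <- as.integer(nodes_per_lamella)
  L <- as.integer(n_lamellae)
  n_nodes <- L * m
  if (is.null(tracked_points)) tracked_points <- seq_len(min(m, n_nodes))
  tracked_points <- as.integer(tracked_points)
  if (any(tracked_points < 1L) || any(tracked_points > n_nodes)) {
    stop("tracked points out of range")
  }
  # polar angle of node j (shared by all lamellae); a single node sits mid-sector
  psi <- if (m == 1L) 0 else (seq_len(m) - 1) / (m - 1) * sector_deg * pi / 180
  radius <- inner_radius + (seq_len(L) - 1) * lamella_spacing
  node_id <- function(i, j) (i - 1L) * m + j
  coords <- matrix(0, n_nodes, 2)
  for (i in seq_len(L)) for (j in seq_len(m)) {
    coords[node_id(i, j), ] <- radius[i] * c(cos(psi[j]), sin(psi[j]))
  }
  # springs: list of (node a, node b, stiffness, unit direction in global xy)
  springs <- list()
  add <- function(a, b, k, dir) {
    springs[[length(springs) + 1L]] <<- list(a = a, b = b, k = k, dir = dir / sqrt(sum(dir^2)))
  }
  for (i in seq_len(L)) {
    if (m > 1L) for (j in seq_len(m - 1L)) {
      a <- node_id(i, j); b <- node_id(i, j + 1L)
      chord <- coords[b, ] - coords[a, ]
      add(a, b, ks[i], chord)                      # axial chord spring
      add(a, b, ks[i] / 2, c(-chord[2], chord[1])) # transverse (shear/bending) spring
    }
  }
  a <- load_angle_deg * pi / 180
  load_dirs <- t(vapply(seq_len(m), function(j) {
    er <- c(cos(psi[j]), sin(psi[j]))
    cos(a) * er + sin(a) * c(-er[2], er[1])
  }, numeric(2)))
  structure(list(n_lamellae = L, nodes_per_lamella = m, coords = coords,
                 psi = psi, radius = radius, lamella_springs = springs,
                 inner_radius = inner_radius, lamella_spacing = lamella_spacing,
                 sector_deg = sector_deg, lamella_stiffness = ks,
                 load = as.numeric(load), load_angle_deg = load_angle_deg,
                 load_dirs = load_dirs, tracked_points = tracked_points,
                 fixed_nodes = (node_id(L, 1L)):(node_id(L, m)),
                 loaded_nodes = seq_len(m)),
            class = "interface_lattice")
}

# assemble the global stiffness matrix over all 2*n_nodes DOFs from the
# lamella springs plus interface springs in the local polar frame
interface_assemble <- function(lattice, k_r, k_t) {
  m <- lattice$nodes_per_lamella
  L <- lattice$n_lamellae
  n_dof <- 2L * L * m
  K <- matrix(0, n_dof, n_dof)
  dofs <- function(node) c(2L * node - 1L, 2L * node)
  add_axial <- function(a, b, k, dir) {
    # energy 1/2 k ((u_b - u_a) . dir)^2
    da <- dofs(a); db <- dofs(b)
    kd <- k * outer(dir, dir)
    K[da, da] <<- K[da, da] + kd
    K[db, db] <<- K[db, db] + kd
    K[da, db] <<- K[da, db] - kd
    K[db, da] <<- K[db, da] - kd
  }
  for (s in lattice$lamella_springs) add_axial(s$a, s$b, s$k, s$dir)
  node_id <- function(i, j) (i - 1L) * m + j
  for (i in seq_len(L - 1L)) for (j in seq_len(m)) {
    er <- c(cos(lattice$psi[j]), sin(lattice$psi[j]))
    et <- c(-er[2], er[1])
    add_axial(node_id(i, j), node_id(i + 1L, j), k_r, er)
    add_axial(node_id(i, j), node_id(i + 1L, j), k_t, et)
  }
  K
}

#' Radial displacements at the tracked interface points
#'
#' Assembles the lattice stiffness for the given interface parameters,
#' fixes the outermost lamella, applies the tension to the inner
#' lamella along its stored pull directions, solves the linear system, and returns the radial displacement
#' (projection onto the local radial direction, mm) at the tracked points
#' in their stored order. A singular system returns a failed output.
#'
#' @param lattice an `interface_lattice`.
#' @param k_r radial interface stiffness (N/mm), > 0.
#' @param k_t tangential interface stiffness (N/mm), > 0.
#' @return `forward_output` of kind `"list"`.
#' @export
interface_displacements <- function(lattice, k_r, k_t) {
  stopifnot(inherits(lattice, "interface_lattice"))
  if (!is.finite(k_r) || k_r <= 0 || !is.finite(k_t) || k_t <= 0) {
    stop("interface stiffnesses must be strictly positive")
  }
  m <- lattice$nodes_per_lamella
  K <- interface_assemble(lattice, k_r, k_t)
  n_nodes <- nrow(lattice$coords)
  fixed_dofs <- as.vector(rbind(2L * lattice$fixed_nodes - 1L, 2L * lattice$fixed_nodes))
  free <- setdiff(seq_len(2L * n_nodes), fixed_dofs)
  f <- numeric(2L * n_nodes)
  per_node <- lattice$load / length(lattice$loaded_nodes)
  for (j in lattice$loaded_nodes) {
    f[c(2L * j - 1L, 2L * j)] <- f[c(2L * j - 1L, 2L * j)] +
      per_node * lattice$load_dirs[(j - 1L) %% m + 1L, ]
  }
  u <- numeric(2L * n_nodes)
  sol <- tryCatch(solve(K[free, free, drop = FALSE], f[free]),
                  error = function(e) NULL)
  if (is.null(sol) || anyNA(sol) || any(!is.finite(sol))) {
    return(forward_failure("list", "singular lattice system"))
  }
  u[free] <- sol
  radial <- vapply(lattice$tracked_points, function(node) {
    j <- (node - 1L) %% m + 1L
    er <- c(cos(lattice$psi[j]), sin(lattice$psi[j]))
    sum(u[c(2L * node - 1L, 2L * node)] * er)
  }, numeric(1))
  forward_output(radial, "list")
}
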