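test_that("greyscale chain reproduces hand-solved series stiffness", {
  # two unit elements at slope 2: k_i = 2, series stiffness 1 N/mm
  lat <- greyscale_lattice(c(1, 1), c(1, 1), c(1, 1), 0.5)
  out <- greyscale_apparent_stiffness(lat, 2)
  expect_false(out$failed)
  expect_equal(out$value, 1)
  # single element: k = E A / L = 4 * 0.5 = 2
  single <- greyscale_lattice(0.5, 1, 1, 0.25)
  expect_equal(greyscale_apparent_stiffness(single, 4)$value, 2)
  # general chain equals the harmonic-series closed form
  set.seed(42)
  lat2 <- random_chain(12L)
  k <- 1234 * lat2$greyscales * lat2$areas / lat2$lengths
  expect_equal(greyscale_apparent_stiffness(lat2, 1234)$value,
               1 / sum(1 / k), tolerance = 1e-12)
})

test_that("greyscale stiffness is exactly linear in the mapping slope", {
  set.seed(7)
  for (i in 1:5) {
    lat <- random_chain(sample(3:15, 1))
    s <- runif(1, 100, 3000)
    k1 <- greyscale_apparent_stiffness(lat, s)$value
    k2 <- greyscale_apparent_stiffness(lat, 2 * s)$value
    expect_equal(k2 / k1, 2, tolerance = 1e-12)
    expect_equal(greyscale_apparent_stiffness(lat, s)$value / s,
                 greyscale_apparent_stiffness(lat, 3.7 * s)$value / (3.7 * s),
                 tolerance = 1e-12)
  }
})

test_that("greyscale solver failure is returned as data, never raised", {
  lat <- greyscale_lattice(c(1, 1, 1), c(1, 1, 1), c(1, 0, 1), 0.5)
  out <- greyscale_apparent_stiffness(lat, 100)
  expect_true(out$failed)
  expect_error(greyscale_apparent_stiffness(lat, -5), "positive")
  expect_error(greyscale_lattice(c(0, 1), c(1, 1), c(1, 1), 0.5), "greyscale")
  expect_error(greyscale_lattice(1, -1, 1, 0.5), "length")
})

test_that("GOH response passes through the origin and obeys fibre recruitment limits", {
  fx <- goh_fixed_params(c10 = 0.1, kappa = 0.1, theta = 30,
                         specimen_area = 100, specimen_height = 10)
  u <- seq(0, 1, length.out = 6)
  out <- goh_force_displacement(2, 40, fx, u)
  expect_false(out$failed)
  expect_equal(out$value$y[1], 0)
  # k1 -> 0: ground-matrix-only response
  tiny <- goh_force_displacement(1e-12, 40, fx, u)$value$y
  matrix_only <- fx$specimen_area * calibfe:::goh_nominal_stress(1 + u / 10, 1e-12, 40, fx)
  th <- 30 * pi / 180
  lam <- 1 + u / 10
  ground <- fx$specimen_area * fx$c10 * (2 * lam - 2 / lam^2)
  expect_equal(tiny, ground, tolerance = 1e-9)
  # fibres entirely in compression (transverse alignment, no dispersion):
  # I4 = 1/lambda < 1 in tension, so the response is matrix-only
  fx_perp <- goh_fixed_params(c10 = 0.1, kappa = 0, theta = 90,
                              specimen_area = 100, specimen_height = 10)
  perp <- goh_force_displacement(5, 40, fx_perp, u)$value$y
  expect_equal(perp, ground, tolerance = 1e-12)
})

test_that("GOH stress matches finite-difference differentiation of the strain energy", {
  fx <- goh_fixed_params(c10 = 0.1, kappa = 0, theta = 30,
                         specimen_area = 1, specimen_height = 1)
  stretches <- seq(1.01, 1.2, length.out = 10)
  u <- stretches - 1
  force <- goh_force_displacement(1, 10, fx, c(0, u))$value$y[-1]
  h <- 1e-6
  fd <- (calibfe:::goh_energy(stretches + h, 1, 10, fx) -
         calibfe:::goh_energy(stretches - h, 1, 10, fx)) / (2 * h)
  expect_equal(force, fd, tolerance = 1e-4)
})

test_that("GOH fibre term approaches the quadratic series limit as k2 -> 0", {
  fx <- goh_fixed_params(c10 = 0.1, kappa = 0.1, theta = 30,
                         specimen_area = 1, specimen_height = 1)
  lam <- seq(1.02, 1.15, length.out = 5)
  th <- fx$theta * pi / 180
  i1 <- lam^2 + 2 / lam; i4 <- lam^2 * cos(th)^2 + sin(th)^2 / lam
  e <- pmax(fx$kappa * (i1 - 3) + (1 - 3 * fx$kappa) * (i4 - 1), 0)
  k1 <- 3
  # closed-form series limit of the two-family fibre energy: k1 * <E>^2
  limit_energy <- fx$c10 * (i1 - 3) + k1 * e^2
  expect_equal(calibfe:::goh_energy(lam, k1, 1e-8, fx), limit_energy,
               tolerance = 1e-4)
})

test_that("GOH response is monotone non-decreasing in k1 and rejects bad inputs", {
  fx <- goh_fixed_params()
  u <- seq(0, 1, length.out = 8)
  k1s <- c(0.5, 1, 2, 4, 8)
  curves <- vapply(k1s, function(k1) goh_force_displacement(k1, 30, fx, u)$value$y,
                   numeric(length(u)))
  expect_true(all(diff(t(curves)) >= -1e-12))
  expect_error(goh_force_displacement(-1, 30, fx, u), "positive")
  expect_error(goh_force_displacement(1, 0, fx, u), "positive")
  expect_error(goh_force_displacement(1, 30, fx, c(0.5, 1)), "increasing from 0")
  # overflow in the fibre exponential returns a failed output
  over <- goh_force_displacement(1, 1e7, fx, c(0, 1, 2))
  expect_true(over$failed)
})

test_that("interface series toy matches the hand-solved spring chain", {
  # three single-node lamellae: two radial interface springs in series;
  # inner displacement 2F/k_r, middle F/k_r, tangential zero
  lat <- interface_lattice(3, 1, load_angle_deg = 0, tracked_points = c(1, 2))
  out <- interface_displacements(lat, 4, 7)
  expect_false(out$failed)
  expect_equal(out$value, c(2 * 1 / 4, 1 / 4), tolerance = 1e-12)
})

test_that("interface lattice is linear in load and radially rigid at large k_r", {
  lat <- interface_lattice(4, 10, tracked_points = 11:26)
  d1 <- interface_displacements(lat, 10, 5)$value
  lat2 <- lat
  lat2$load <- 2 * lat$load
  d2 <- interface_displacements(lat2, 10, 5)$value
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  # rigid radial coupling: facing nodes across an interface coincide
  lat3 <- interface_lattice(3, 10, tracked_points = c(5, 15))
  dd <- interface_displacements(lat3, 1e10, 5)$value
  expect_lt(abs(dd[1] - dd[2]), 1e-6)
})

test_that("interface solve agrees with an independently assembled dense system", {
  lat <- interface_lattice(4, 9, tracked_points = 10:25)
  k_r <- 13; k_t <- 4
  m <- lat$nodes_per_lamella
  n_dof <- 2L * nrow(lat$coords)
  # independent assembly: rank-1 incidence outer products per spring
  K <- matrix(0, n_dof, n_dof)
  add_spring <- function(a, b, k, dir) {
    g <- numeric(n_dof)
    g[c(2 * a - 1, 2 * a)] <- dir
    g[c(2 * b - 1, 2 * b)] <- -dir
    K <<- K + k * tcrossprod(g)
  }
  for (s in lat$lamella_springs) add_spring(s$a, s$b, s$k, s$dir)
  for (i in seq_len(lat$n_lamellae - 1)) for (j in seq_len(m)) {
    er <- c(cos(lat$psi[j]), sin(lat$psi[j]))
    add_spring((i - 1) * m + j, i * m + j, k_r, er)
    add_spring((i - 1) * m + j, i * m + j, k_t, c(-er[2], er[1]))
  }
  fixed <- as.vector(rbind(2 * lat$fixed_nodes - 1, 2 * lat$fixed_nodes))
  free <- setdiff(seq_len(n_dof), fixed)
  f <- numeric(n_dof)
  for (j in lat$loaded_nodes) {
    f[c(2 * j - 1, 2 * j)] <- lat$load / length(lat$loaded_nodes) * lat$load_dirs[j, ]
  }
  u <- numeric(n_dof)
  u[free] <- solve(K[free, free], f[free])
  oracle <- vapply(lat$tracked_points, function(node) {
    j <- (node - 1) %% m + 1
    sum(u[c(2 * node - 1, 2 * node)] * c(cos(lat$psi[j]), sin(lat$psi[j])))
  }, numeric(1))
  expect_equal(interface_displacements(lat, k_r, k_t)$value, oracle,
               tolerance = 1e-10)
})

test_that("interface singular system returns a failed output", {
  lat <- interface_lattice(3, 4, tracked_points = c(1, 2))
  lat$fixed_nodes <- integer(0)  # free-floating: rigid-body modes
  out <- interface_displacements(lat, 5, 5)
  expect_true(out$failed)
  expect_error(interface_displacements(lat, -1, 5), "positive")
  expect_error(interface_lattice(1, 4), "lamellae")
})
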