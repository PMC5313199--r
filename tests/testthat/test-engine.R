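two_bead_system <- function(r = 2^(1 / 6) * 2.0) {
  atoms <- data.frame(
    serial = 1:2, name = c("B1", "B2"), resname = c("REC", "LIG"),
    chain = c("A", "B"), resid = 1L, element = "X", radius = 1, mass = 12,
    stringsAsFactors = FALSE
  )
  molecular_system(atoms, rbind(c(0, 0, 0), c(r, 0, 0)), 1L, 2L)
}

test_that("LJ dimer at the minimum has energy -epsilon and zero force", {
  sys <- two_bead_system()
  ff <- toy_forcefield(sys, sigma = 2.0, epsilon = 1.3)
  ev <- compute_energy_forces(sys, ff, NULL, sys$coords)
  expect_equal(ev$energy, -1.3, tolerance = 1e-12)
  expect_lt(max(abs(ev$forces)), 1e-10)
  expect_equal(interaction_energy(sys, ff, sys$coords), -1.3, tolerance = 1e-12)
})

test_that("restraint energies follow the k*delta^2 convention", {
  sys <- two_bead_system()
  ff <- toy_forcefield(sys, sigma = 1, epsilon = 0)
  rs <- restraint_set(positional = data.frame(i = 2L, x = 0, y = 0, z = 0, k = 0.5))
  coords <- rbind(c(0, 0, 0), c(2, 0, 0)) # displaced 2 A
  ev <- compute_energy_forces(sys, ff, rs, coords)
  expect_equal(unname(ev$breakdown["positional"]), 0.5 * 4)
  rs2 <- restraint_set(pair_distance = data.frame(i = 1L, j = 2L, r_ref = 5, k = 2.5))
  ev2 <- compute_energy_forces(sys, ff, rs2, coords)
  expect_equal(unname(ev2$breakdown["pair_distance"]), 2.5 * (2 - 5)^2)
})

test_that("total forces match finite differences on random configurations", {
  toy <- make_sticky_receptor(
    n_receptor_beads = 16, n_ligand_beads = 3,
    grid_n = 400
  )
  g <- select_surface_atoms(toy$system)
  w <- bias_window(2, 4, 2.5)
  bias_fn <- function(x) evaluate_bias(g, x, w)
  efun <- function(x) {
    compute_energy_forces(toy$system, toy$ff, toy$restraints, x, bias = bias_fn)$energy
  }
  set.seed(21)
  for (case in 1:3) {
    coords <- toy$system$coords + matrix(stats::rnorm(n_atoms(toy$system) * 3, sd = 0.3), ncol = 3)
    ev <- compute_energy_forces(toy$system, toy$ff, toy$restraints, coords, bias = bias_fn)
    pick <- sample(n_atoms(toy$system), 5)
    num <- oracle_num_forces(efun, coords, atoms = pick)
    expect_lt(max(abs(num[pick, ] - ev$forces[pick, ]) / pmax(1, abs(num[pick, ]))), 1e-5)
  }
})

test_that("non-finite energies name the offending term", {
  sys <- two_bead_system()
  ff <- toy_forcefield(sys, sigma = 2, epsilon = 1)
  coords <- rbind(c(0, 0, 0), c(NaN, 0, 0))
  expect_error(
    compute_energy_forces(sys, ff, NULL, coords),
    "non-finite energy.*pair"
  )
})

test_that("zero force and zero friction give exact free flight", {
  sys <- two_bead_system(r = 50)
  ff <- toy_forcefield(sys, sigma = 1, epsilon = 0)
  force_fn <- function(x) compute_energy_forces(sys, ff, NULL, x)
  v0 <- rbind(c(1, -2, 0.5), c(0.25, 0, -1))
  st <- sim_state(sys$coords, sys$atoms$mass, 300, seed = 1, velocities = v0)
  st <- langevin_step(st, force_fn, dt = 0.02, gamma = 0)
  expect_equal(st$coords, sys$coords + v0 * 0.02, tolerance = 1e-14)
  expect_equal(st$velocities, v0, tolerance = 1e-14)
})

test_that("the gamma = 0 limit conserves energy for an LJ dimer", {
  sys <- two_bead_system(r = 2.4)
  ff <- toy_forcefield(sys, sigma = 2, epsilon = 1)
  force_fn <- function(x) compute_energy_forces(sys, ff, NULL, x)
  st <- sim_state(sys$coords, sys$atoms$mass, 300,
    seed = 4,
    velocities = matrix(0, 2, 3)
  )
  e0 <- compute_energy_forces(sys, ff, NULL, st$coords)$energy
  drift <- 0
  for (chunk in 1:10) {
    out <- run_segment(st, force_fn, 1000, dt = 1e-4, gamma = 0)
    st <- out$state
    e <- st$energy + kinetic_energy(st)
    drift <- max(drift, abs(e - e0))
  }
  expect_lt(drift, 1e-4)
})

test_that("thermostat reaches equipartition for a harmonic degree of freedom", {
  # U = 0.5 x^2 (positional restraint k = 0.5): variance k_B T, stiffness 1
  sys <- two_bead_system(r = 50)
  ff <- toy_forcefield(sys, sigma = 1, epsilon = 0)
  rs <- restraint_set(positional = data.frame(i = 2L, x = 50, y = 0, z = 0, k = 0.5))
  force_fn <- function(x) compute_energy_forces(sys, ff, rs, x)
  frozen <- rbind(c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE))
  st <- sim_state(sys$coords, sys$atoms$mass, 300, seed = 11, frozen = frozen)
  out <- run_segment(st, force_fn, 2e5, dt = 0.01, gamma = 2, record_every = 10)
  xs <- vapply(out$frames, function(f) f[2, 1] - 50, numeric(1))
  kbt <- 0.0019872041 * 300
  expect_lt(abs(stats::var(xs) - kbt) / kbt, 0.05)
})

test_that("the time-averaged kinetic temperature tracks the target", {
  toy <- make_sticky_receptor(n_receptor_beads = 16, grid_n = 400)
  force_fn <- function(x) compute_energy_forces(toy$system, toy$ff, toy$restraints, x)
  st <- sim_state(toy$system$coords, toy$system$atoms$mass, 300, seed = 19)
  temps <- numeric(100)
  for (k in 1:100) {
    out <- run_segment(st, force_fn, 200, dt = 0.005, gamma = 1)
    st <- out$state
    temps[k] <- kinetic_temperature(st)
  }
  expect_lt(abs(mean(temps[21:100]) - 300) / 300, 0.03)
})

test_that("segments are bit-reproducible and record at the stated stride", {
  toy <- make_sticky_receptor(n_receptor_beads = 16, grid_n = 400)
  force_fn <- function(x) compute_energy_forces(toy$system, toy$ff, toy$restraints, x)
  run_once <- function() {
    st <- sim_state(toy$system$coords, toy$system$atoms$mass, 300, seed = 8)
    run_segment(st, force_fn, 100, dt = 0.005, gamma = 0.1, record_every = 10)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$state$coords, b$state$coords)
  expect_identical(a$frames, b$frames)
  expect_length(a$frames, 10L)
  # record_every > n_steps: no interior frames, final state still advanced
  st <- sim_state(toy$system$coords, toy$system$atoms$mass, 300, seed = 8)
  out <- run_segment(st, force_fn, 5, dt = 0.005, gamma = 0.1, record_every = 10)
  expect_length(out$frames, 0L)
  expect_equal(out$state$step, 5L)
})

test_that("sampled positions match the Boltzmann density of a 3-D well", {
  # isotropic positional restraint k = 1 -> independent Gaussians, sd^2 = kBT/2
  sys <- two_bead_system(r = 50)
  ff <- toy_forcefield(sys, sigma = 1, epsilon = 0)
  rs <- restraint_set(positional = data.frame(i = 2L, x = 50, y = 0, z = 0, k = 1))
  force_fn <- function(x) compute_energy_forces(sys, ff, rs, x)
  frozen <- rbind(rep(TRUE, 3), rep(FALSE, 3))
  st <- sim_state(sys$coords, sys$atoms$mass, 300, seed = 13, frozen = frozen)
  out <- run_segment(st, force_fn, 1e5, dt = 0.01, gamma = 2, record_every = 3)
  xs <- do.call(rbind, out$frames)[, ]
  dev <- cbind(
    vapply(out$frames, function(f) f[2, 1] - 50, numeric(1)),
    vapply(out$frames, function(f) f[2, 2], numeric(1)),
    vapply(out$frames, function(f) f[2, 3], numeric(1))
  )
  sd_th <- sqrt(0.0019872041 * 300 / 2)
  ks <- suppressWarnings(stats::ks.test(as.numeric(dev) / sd_th, "pnorm"))
  expect_lt(unname(ks$statistic), 0.02)
})
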