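random_structure <- function(n, seed = 1, spread = 5) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -spread, spread), n, 3)
}

test_that("superposition recovers exact rigid transforms", {
  A <- random_structure(10, seed = 1)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  R <- rotation_about(c(0, 0, 1), pi / 2)
  B <- A %*% t(R) + matrix(c(3, -1, 2), 10, 3, byrow = TRUE)
  tr <- kabsch_superpose(A, B)
  expect_lt(tr$rmsd, 1e-10)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
})

test_that("superposition matches the quaternion oracle on random pairs", {
  for (seed in 1:5) {
    A <- random_structure(10, seed = seed)
    B <- random_structure(10, seed = seed + 100)
    got <- kabsch_superpose(A, B)
    ref <- oracle_quaternion_rmsd(A, B)
    expect_equal(got$rmsd, ref$rmsd, tolerance = 1e-9)
    expect_equal(det(got$rotation), 1, tolerance = 1e-10)
  }
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_superpose(random_structure(5), random_structure(5), selection = 1:2), "3")
})

test_that("ligand RMSD uses receptor superposition without ligand re-fit", {
  ref <- random_structure(12, seed = 3)
  rsel <- 1:8
  lsel <- 9:12
  expect_equal(ligand_rmsd(ref, ref, rsel, lsel), 0, tolerance = 1e-12)
  # rigid 3 A ligand translation with receptor fixed -> exactly 3
  fr <- ref
  fr[lsel, 1] <- fr[lsel, 1] + 3
  expect_equal(ligand_rmsd(fr, ref, rsel, lsel), 3.0, tolerance = 1e-10)
  # random frame equals the two-step oracle
  fr2 <- ref + matrix(stats::rnorm(36, sd = 0.8), 12, 3)
  tr <- oracle_quaternion_rmsd(fr2[rsel, ], ref[rsel, ])
  fitted <- sweep(fr2, 2, colMeans(fr2[rsel, ])) %*% tr$rotation
  fitted <- sweep(fitted, 2, colMeans(ref[rsel, ]), `+`)
  oracle <- sqrt(mean(rowSums((fitted[lsel, ] - ref[lsel, ])^2)))
  expect_equal(ligand_rmsd(fr2, ref, rsel, lsel), oracle, tolerance = 1e-9)
})

test_that("ligand RMSD is invariant under global rigid transforms", {
  ref <- random_structure(12, seed = 5)
  fr <- ref + matrix(stats::rnorm(36, sd = 0.5), 12, 3)
  base <- ligand_rmsd(fr, ref, 1:8, 9:12)
  for (seed in 1:5) {
    set.seed(seed)
    R <- rotation_about(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    moved <- fr %*% t(R) + matrix(stats::rnorm(3, sd = 10), 12, 3, byrow = TRUE)
    expect_lt(abs(ligand_rmsd(moved, ref, 1:8, 9:12) - base), 1e-9)
  }
})

test_that("near-native fractions count strictly and nest across thresholds", {
  expect_equal(near_native_fraction(c(0.5, 1.0, 1.9), 2), 1.0)
  expect_equal(near_native_fraction(c(1.0, 3.0, 5.0), 4), 2 / 3)
  # threshold is strict "<"
  expect_equal(near_native_fraction(c(2.0, 2.0), 2), 0)
  # window restriction equals slicing by hand
  set.seed(8)
  series <- stats::runif(100, 0, 6)
  win <- 51:100
  expect_equal(
    near_native_fraction(series, 3, win),
    mean(series[win] < 3)
  )
  expect_error(near_native_fraction(series, 3, 90:110), "outside")
  expect_error(near_native_fraction(numeric(), 3), "empty")
  # nesting
  for (seed in 1:5) {
    set.seed(seed)
    s <- stats::runif(50, 0, 8)
    expect_lte(near_native_fraction(s, 2), near_native_fraction(s, 4))
  }
})

test_that("first passage returns the minimal index or never", {
  expect_equal(first_passage(c(1.0, 5.0), 2), 1L)
  expect_equal(first_passage(c(5, 4.5, 1.9), 2), 3L)
  expect_true(is.na(first_passage(c(5, 4.5, 3.2), 2)))
})

test_that("leader clustering is deterministic and certifies its radius", {
  ref <- random_structure(12, seed = 2)
  rsel <- 1:8
  lsel <- 9:12
  # all frames identical -> one cluster
  frames <- replicate(6, ref, simplify = FALSE)
  cl <- leader_cluster(frames, ref, rsel, lsel, radius = 4)
  expect_equal(length(unique(cl$assignment)), 1L)
  expect_equal(cl$sizes$size, 6L)
  # two tight bundles 10 A apart -> two clusters with the bundle sizes
  bundle2 <- ref
  bundle2[lsel, 1] <- bundle2[lsel, 1] + 10
  frames <- c(
    replicate(4, ref, simplify = FALSE),
    replicate(3, bundle2, simplify = FALSE)
  )
  set.seed(4)
  frames <- lapply(frames, function(f) {
    f[lsel, ] <- f[lsel, ] + matrix(stats::rnorm(12, sd = 0.2), 4, 3)
    f
  })
  cl <- leader_cluster(frames, ref, rsel, lsel, radius = 4)
  expect_equal(sort(cl$sizes$size), c(3L, 4L))
  # certified post-condition + order determinism on a random set
  frames <- lapply(1:20, function(i) {
    f <- ref
    f[lsel, ] <- f[lsel, ] + matrix(stats::rnorm(12, sd = 3), 4, 3)
    f
  })
  cl1 <- leader_cluster(frames, ref, rsel, lsel, radius = 4)
  cl2 <- leader_cluster(frames, ref, rsel, lsel, radius = 4)
  expect_identical(cl1$assignment, cl2$assignment)
  lig <- lapply(frames, function(f) {
    tr <- kabsch_superpose(f, ref, rsel)
    (f %*% tr$rotation + matrix(tr$translation, 12, 3, byrow = TRUE))[lsel, ]
  })
  for (f in seq_along(frames)) {
    leader <- cl1$leaders[cl1$assignment[f]]
    d <- sqrt(mean(rowSums((lig[[f]] - lig[[leader]])^2)))
    expect_lt(d, 4)
  }
})

test_that("interaction-energy series isolates cross nonbonded terms", {
  toy <- make_sticky_receptor(n_receptor_beads = 16, grid_n = 400)
  g <- select_surface_atoms(toy$system)
  store <- run_hremd(toy$system, toy$ff, toy$restraints, g, toy_ladder(),
    n_steps = 100, exchange_interval = 20, seed = 6, dt = 0.005,
    record_every = 20
  )
  ser <- interaction_energy_series(store, toy$system, toy$ff,
    replica = 1,
    reference = toy$native_pose
  )
  expect_equal(nrow(ser), 5L)
  expect_true(all(c("step", "energy", "rmsd") %in% names(ser)))
  # oracle: plain double loop over cross pairs with combined LJ parameters
  fr <- store$frames[[1]][[3]]
  e <- 0
  for (r in seq_along(toy$system$receptor_idx)) {
    for (l in seq_along(toy$system$ligand_idx)) {
      dv <- fr[toy$system$receptor_idx[r], ] - fr[toy$system$ligand_idx[l], ]
      d2 <- sum(dv^2)
      sig <- toy$ff$sig_cross[r, l]
      eps <- toy$ff$eps_cross[r, l]
      e <- e + 4 * eps * ((sig^2 / d2)^6 - (sig^2 / d2)^3)
    }
  }
  expect_equal(ser$energy[3], e, tolerance = 1e-10)
  # partners at infinite separation -> 0
  far <- toy$system$coords
  far[toy$system$ligand_idx, ] <- far[toy$system$ligand_idx, ] + 1e6
  expect_equal(interaction_energy(toy$system, toy$ff, far), 0, tolerance = 1e-12)
})
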