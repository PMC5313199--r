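pair_list <- function(d, ri = seq_along(d), li = seq_along(d) + 1000L, cutoff = 10) {
  structure(list(ri = ri, li = li, d = d, cutoff = cutoff), class = "ContactPairList")
}

test_that("weighted mean distance reproduces hand cases", {
  expect_equal(weighted_mean_distance(pair_list(5.0), 12), 5.0)
  expect_equal(weighted_mean_distance(pair_list(rep(7.3, 12)), 6), 7.3)
  expect_equal(weighted_mean_distance(pair_list(rep(7.3, 12)), 12), 7.3)
})

test_that("weighted mean distance matches the double-loop oracle", {
  set.seed(11)
  for (case in 1:5) {
    rc <- matrix(stats::runif(9 * 3, 0, 8), 9, 3)
    lc <- matrix(stats::runif(7 * 3, 2, 10), 7, 3)
    sys <- make_random_test_system(9, 7, seed = case)
    sys$coords[1:9, ] <- rc
    sys$coords[9 + 1:7, ] <- lc
    g <- all_atom_groups(sys)
    pl <- build_contact_pairs(g, sys$coords, cutoff = 10)
    expect_gt(n_pairs(pl), 0L)
    for (p in c(6, 12)) {
      ref <- oracle_weighted_mean(rc, lc, p, cutoff = 10)
      got <- weighted_mean_distance(pl, p)
      expect_equal(got, ref, tolerance = 1e-12)
      reff <- oracle_weighted_mean(rc, lc, p, cutoff = 10, normalization = "full")
      gotf <- weighted_mean_distance(pl, p, normalization = "full", n_full = 9 * 7)
      expect_equal(gotf, reff, tolerance = 1e-12)
    }
  }
})

test_that("power-mean inequality and min-distance bounds hold", {
  set.seed(12)
  for (case in 1:20) {
    d <- stats::runif(sample(2:40, 1), 3, 10)
    d6 <- weighted_mean_distance(pair_list(d), 6)
    d12 <- weighted_mean_distance(pair_list(d), 12)
    expect_lte(d12, d6 + 1e-12)
    expect_gte(d12, min(d) - 1e-12)
    expect_lte(d12, min(d) * length(d)^(1 / 12) + 1e-12)
  }
  # equality iff all distances equal
  expect_equal(
    weighted_mean_distance(pair_list(rep(4, 5)), 6),
    weighted_mean_distance(pair_list(rep(4, 5)), 12)
  )
})

test_that("evaluation is scale-stable down to the numerical floor", {
  d <- c(0.06, 0.08, 0.5, 0.9)
  big <- weighted_mean_distance(pair_list(d * 100), 12)
  small <- weighted_mean_distance(pair_list(d), 12)
  expect_equal(small * 100, big, tolerance = 1e-12)
  expect_true(is.finite(small))
  expect_error(weighted_mean_distance(pair_list(c(0.01, 5))), "0.05")
  expect_error(weighted_mean_distance(pair_list(numeric())), "guard")
})

test_that("window energy follows the piecewise-quadratic form", {
  w <- bias_window(4.0, 6.0, 2.5)
  expect_equal(bias_energy(5.0, w), 0)
  expect_equal(bias_energy(3.0, w), 2.5)
  expect_equal(bias_energy(7.0, bias_window(4, 6, 5.0)), 5.0)
  # C0/C1 continuity at both edges
  eps <- 1e-8
  for (edge in c(4.0, 6.0)) {
    expect_lt(abs(bias_energy(edge + eps, w) - bias_energy(edge - eps, w)), 1e-12)
    num_deriv <- (bias_energy(edge + eps, w) - bias_energy(edge - eps, w)) / (2 * eps)
    expect_lt(abs(num_deriv), 1e-6)
  }
  expect_error(bias_window(6, 4), "d_low < d_up")
  expect_error(bias_window(-1, 4), "d_low")
})

test_that("bias forces are the exact negative gradient", {
  sys <- make_random_test_system(6, 4, seed = 3, spread = 2.5)
  g <- all_atom_groups(sys)
  for (w in list(bias_window(8, 12, 2.5), bias_window(1, 2, 5.0))) {
    pl <- build_contact_pairs(g, sys$coords, cutoff = 10)
    bf <- bias_forces(sys$coords, pl, w)
    efun <- function(x) {
      p <- build_contact_pairs(g, x, cutoff = 10)
      bias_energy(weighted_mean_distance(p, 12), w)
    }
    num <- oracle_num_forces(efun, sys$coords)
    expect_lt(max(abs(num - bf$forces) / pmax(1, abs(num))), 1e-5)
    # net force and torque vanish
    expect_lt(max(abs(colSums(bf$forces))), 1e-10)
    tq <- colSums(cbind(
      sys$coords[, 2] * bf$forces[, 3] - sys$coords[, 3] * bf$forces[, 2],
      sys$coords[, 3] * bf$forces[, 1] - sys$coords[, 1] * bf$forces[, 3],
      sys$coords[, 1] * bf$forces[, 2] - sys$coords[, 2] * bf$forces[, 1]
    ))
    expect_lt(max(abs(tq)), 1e-9)
  }
})

test_that("forces vanish inside the window and concentrate on short contacts", {
  sys <- make_random_test_system(6, 4, seed = 5, spread = 2.5)
  g <- all_atom_groups(sys)
  pl <- build_contact_pairs(g, sys$coords, cutoff = 10)
  d_ave <- weighted_mean_distance(pl, 12)
  inside <- bias_window(d_ave - 1, d_ave + 1, 2.5)
  bf <- bias_forces(sys$coords, pl, inside)
  expect_true(all(bf$forces == 0))

  # two pairs at 4 and 9 A: the short pair dominates by ~(9/4)^13 / n
  coords <- rbind(c(0, 0, 0), c(0, 30, 0), c(4, 0, 0), c(0, 39, 0))
  atoms <- data.frame(
    serial = 1:4, name = "B", resname = "X", chain = c("A", "A", "B", "B"),
    resid = 1L, element = "X", radius = 1, mass = 12, stringsAsFactors = FALSE
  )
  sys2 <- molecular_system(atoms, coords, 1:2, 3:4)
  g2 <- all_atom_groups(sys2)
  pl2 <- build_contact_pairs(g2, coords, cutoff = 10)
  expect_equal(sort(pl2$d), c(4, 9))
  w <- bias_window(6, 8, 2.5) # d_ave below window: repulsion active
  bf2 <- bias_forces(coords, pl2, w)
  f_short <- sqrt(sum(bf2$forces[3, ]^2))
  f_long <- sqrt(sum(bf2$forces[4, ]^2))
  expect_gt(f_short / f_long, (9 / 4)^13 / n_pairs(pl2))
})

test_that("bias forces remain conservative around a closed loop", {
  sys <- make_random_test_system(5, 3, seed = 9, spread = 2.5)
  g <- all_atom_groups(sys)
  w <- bias_window(9, 12, 2.5)
  # drag one ligand atom around a 100-point closed circle, integrating F.dx
  idx <- sys$ligand_idx[1]
  theta <- seq(0, 2 * pi, length.out = 101)
  center <- sys$coords[idx, ]
  path <- cbind(center[1] + 0.4 * cos(theta), center[2] + 0.4 * sin(theta), center[3])
  work <- 0
  for (k in seq_len(100)) {
    mid <- sys$coords
    mid[idx, ] <- (path[k, ] + path[k + 1, ]) / 2
    pl <- build_contact_pairs(g, mid, cutoff = 10)
    f <- bias_forces(mid, pl, w)$forces[idx, ]
    work <- work + sum(f * (path[k + 1, ] - path[k, ]))
  }
  expect_lt(abs(work), 1e-6)
})

test_that("dissociation guard activates only without contacts", {
  sys <- make_random_test_system(4, 3, seed = 2)
  g <- all_atom_groups(sys)
  # an 8 A pair exists: guard quiet
  coords <- rbind(
    c(0, 0, 0), c(0, 6, 0), c(0, -6, 0), c(0, 12, 0),
    c(8, 0, 0), c(30, 0, 0), c(40, 0, 0)
  )
  gd <- dissociation_guard(g, coords, cutoff = 10, k = 2.5)
  expect_equal(gd$energy, 0)
  expect_false(gd$active)
  expect_true(all(gd$forces == 0))
  # closest pair at 12 A, k = 2.5 -> 2.5 * 4 = 10
  coords2 <- coords
  coords2[5:7, 1] <- c(12, 40, 50)
  gd2 <- dissociation_guard(g, coords2, cutoff = 10, k = 2.5)
  expect_true(gd2$active)
  expect_equal(gd2$energy, 10.0)
  # equal-and-opposite forces along the pair axis
  expect_equal(gd2$forces[1, ], -gd2$forces[5, ])
  expect_equal(abs(gd2$forces[1, 1]), 2 * 2.5 * 2.0)
  # finite differences across the guard
  efun <- function(x) dissociation_guard(g, x, 10, 2.5)$energy
  num <- oracle_num_forces(efun, coords2, atoms = c(1, 5))
  expect_lt(max(abs(num[c(1, 5), ] - gd2$forces[c(1, 5), ])), 1e-6)
})

test_that("guard tie-break picks the lowest lexicographic pair", {
  coords <- rbind(c(0, 0, 0), c(0, 20, 0), c(12, 0, 0), c(12, 20, 0))
  atoms <- data.frame(
    serial = 1:4, name = "B", resname = "X", chain = c("A", "A", "B", "B"),
    resid = 1L, element = "X", radius = 1, mass = 12, stringsAsFactors = FALSE
  )
  sys <- molecular_system(atoms, coords, 1:2, 3:4)
  g <- all_atom_groups(sys)
  cp <- closest_surface_pair(g, coords)
  # both (1,3) and (2,4) sit at exactly 12 A
  expect_equal(c(cp$ri, cp$li), c(1L, 3L))
})

test_that("evaluate_bias dispatches exclusively between window and guard", {
  toy <- make_sticky_receptor(n_receptor_beads = 16, grid_n = 400)
  g <- select_surface_atoms(toy$system)
  w <- bias_window(2, 4, 2.5)
  bound <- evaluate_bias(g, toy$system$coords, w)
  expect_false(bound$guard_active)
  expect_gt(bound$n_pairs, 0L)
  expect_true(is.finite(bound$d_ave12))

  apart <- toy$system$coords
  apart[toy$system$ligand_idx, ] <- apart[toy$system$ligand_idx, ] + c(60, 0, 0)
  far <- evaluate_bias(g, apart, w)
  expect_true(far$guard_active)
  expect_equal(far$n_pairs, 0L)
  expect_true(is.na(far$d_ave12))
  expect_gt(far$energy, 0)
})

test_that("ladder presets are stored verbatim and validated", {
  l6 <- ladder_preset("ladder6")
  expect_length(l6$windows, 6L)
  expect_equal(l6$windows[[1]]$d_low, 4.0)
  expect_equal(l6$windows[[4]]$d_up, 7.15) # verbatim non-monotone upper bound
  expect_length(ladder_preset("ladder10")$windows, 10L)
  l12 <- ladder_preset("ladder12", k_f = 5)
  expect_length(l12$windows, 12L)
  expect_equal(l12$windows[[12]]$k_f, 5)
  # user ladders: strict low ordering and neighbour overlap enforced
  expect_error(
    replica_ladder(list(bias_window(4, 6), bias_window(4, 7))),
    "strictly"
  )
  expect_error(
    replica_ladder(list(bias_window(4, 6), bias_window(6.5, 8))),
    "overlap"
  )
  expect_warning(
    replica_ladder(list(bias_window(4, 8), bias_window(5, 7))),
    "upper bounds"
  )
})
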