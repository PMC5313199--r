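# Coarse-grained Langevin dynamics engine: bead-level Lennard-Jones force
# field, harmonic restraint schemes and a BAOAB-discretised integrator.
# Units: Angstrom, kcal/mol, ps, amu. Harmonic terms use the Amber-style
# convention E = k * delta^2 (no factor 1/2).

#' Bead-level toy force field
#'
#' Lennard-Jones pair terms between the receptor and ligand beads and between
#' non-bonded ligand beads, harmonic bonds within the ligand, and per-receptor
#' -bead depth multipliers encoding "sticky" decoy sites and one native site.
#'
#' @param system a `MolecularSystem`.
#' @param sigma per-atom LJ diameters (Angstrom); scalar recycled.
#' @param epsilon per-atom LJ well depths (kcal/mol); scalar recycled.
#'   Cross-pair parameters follow Lorentz-Berthelot combination.
#' @param site_depth named or per-receptor-atom numeric vector of absolute
#'   well-depth overrides (kcal/mol) for receptor beads: for a receptor bead
#'   with an override, the cross-pair depth against every ligand bead becomes
#'   the override value. NA entries keep the combined default.
#' @param bonds data.frame(i, j, r0, k): harmonic bonds E = k (r - r0)^2.
#' @return An object of class `ToyForceField`.
#' @export
toy_forcefield <- function(system, sigma = 2.0, epsilon = 0.3,
                           site_depth = NULL, bonds = NULL) {
  n <- n_atoms(system)
  sigma <- rep_len(sigma, n)
  epsilon <- rep_len(epsilon, n)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  ri <- system$receptor_idx
  li <- system$ligand_idx
  sig_cross <- outer(sigma[ri], sigma[li], function(a, b) (a + b) / 2)
  eps_cross <- outer(epsilon[ri], epsilon[li], function(a, b) sqrt(a * b))
  if (!is.null(site_depth)) {
    if (length(site_depth) != length(ri)) {
      stop("site_depth must have one entry per receptor atom (use NA for defaults)")
    }
    ov <- which(!is.na(site_depth))
    eps_cross[ov, ] <- site_depth[ov]
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric())
  }
  if (nrow(bonds) > 0 && any(bonds$k < 0)) stop("bond force constants must be >= 0")
  # non-bonded intra-ligand pairs: all ligand pairs not directly bonded
  lig_pairs <- NULL
  if (length(li) > 1L) {
    cmb <- utils::combn(li, 2L)
    bonded <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    keep <- !(paste(pmin(cmb[1, ], cmb[2, ]), pmax(cmb[1, ], cmb[2, ])) %in% bonded)
    lig_pairs <- cmb[, keep, drop = FALSE]
  }
  # per-atom LJ parameters for intra-ligand pairs
  structure(
    list(
      sigma = sigma, epsilon = epsilon,
      sig_cross = sig_cross, eps_cross = eps_cross,
      receptor_idx = ri, ligand_idx = li,
      bonds = bonds, lig_pairs = lig_pairs,
      site_depth = site_depth,
      # plain-vector caches for the per-step force loop
      b_i = as.integer(bonds$i), b_j = as.integer(bonds$j),
      b_r0 = as.numeric(bonds$r0), b_k = as.numeric(bonds$k),
      lp_i = if (is.null(lig_pairs)) integer() else as.integer(lig_pairs[1L, ]),
      lp_j = if (is.null(lig_pairs)) integer() else as.integer(lig_pairs[2L, ]),
      lp_sig = if (is.null(lig_pairs)) numeric() else (sigma[lig_pairs[1L, ]] + sigma[lig_pairs[2L, ]]) / 2,
      lp_eps = if (is.null(lig_pairs)) numeric() else sqrt(epsilon[lig_pairs[1L, ]] * epsilon[lig_pairs[2L, ]])
    ),
    class = "ToyForceField"
  )
}

#' Harmonic restraint set
#'
#' Positional restraints E = k |x - x_ref|^2 (the receptor-anchoring scheme,
#' default k = 0.5 kcal mol^-1 A^-2) and pair-distance restraints
#' E = k (d_ij - r_ref)^2 (the all-pair internal-geometry scheme, default
#' k = 2.5 kcal mol^-1 A^-2).
#'
#' @param positional data.frame(i, x, y, z, k) or NULL.
#' @param pair_distance data.frame(i, j, r_ref, k) or NULL.
#' @return An object of class `RestraintSet`.
#' @export
restraint_set <- function(positional = NULL, pair_distance = NULL) {
  if (is.null(positional)) {
    positional <- data.frame(i = integer(), x = numeric(), y = numeric(), z = numeric(), k = numeric())
  }
  if (is.null(pair_distance)) {
    pair_distance <- data.frame(i = integer(), j = integer(), r_ref = numeric(), k = numeric())
  }
  if (nrow(positional) > 0 && any(positional$k < 0)) stop("restraint force constants must be >= 0")
  if (nrow(pair_distance) > 0 && any(pair_distance$k < 0)) stop("restraint force constants must be >= 0")
  structure(
    list(
      positional = positional, pair_distance = pair_distance,
      p_i = as.integer(positional$i),
      p_ref = cbind(positional$x, positional$y, positional$z),
      p_k = as.numeric(positional$k),
      q_i = as.integer(pair_distance$i), q_j = as.integer(pair_distance$j),
      q_r = as.numeric(pair_distance$r_ref), q_k = as.numeric(pair_distance$k)
    ),
    class = "RestraintSet"
  )
}

lj_pair_terms <- function(rc, lc, sig, eps) {
  # rc: m x 3, lc: n x 3; sig, eps: m x n matrices
  d2 <- outer(rowSums(rc^2), rowSums(lc^2), `+`) - 2 * tcrossprod(rc, lc)
  d2 <- pmax(d2, 1e-12)
  inv2 <- sig^2 / d2
  inv6 <- inv2^3
  e <- 4 * eps * (inv6^2 - inv6)
  # dE/dr / r  (so force vector on "r" atom = -(dE/dr/r) * (x_r - x_l))
  dEdr_over_r <- 4 * eps * (-12 * inv6^2 + 6 * inv6) / d2
  list(energy = sum(e), dEdr_over_r = dEdr_over_r)
}

#' Total energy and forces of the toy system
#'
#' Aggregates the bead force field, the restraint schemes and an optional
#' biasing-term closure; forces are the exact negative gradient of the total.
#'
#' @param system a `MolecularSystem`.
#' @param ff a `ToyForceField`.
#' @param restraints a `RestraintSet` (or NULL).
#' @param coords N x 3 frame.
#' @param bias optional closure `function(coords)` returning
#'   list(energy, forces, d_ave12, n_pairs, guard_active) as produced by
#'   [evaluate_bias()].
#' @return list(energy, forces, breakdown, bias_diag) where breakdown names
#'   {pair, ligand_pair, bond, positional, pair_distance, bias, guard}.
#' @export
compute_energy_forces <- function(system, ff, restraints, coords, bias = NULL) {
  if (!is.matrix(coords)) coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  forces <- matrix(0, n, 3L)
  breakdown <- c(
    pair = 0, ligand_pair = 0, bond = 0, positional = 0,
    pair_distance = 0, bias = 0, guard = 0
  )

  ri <- ff$receptor_idx
  li <- ff$ligand_idx
  rc <- coords[ri, , drop = FALSE]
  lc <- coords[li, , drop = FALSE]

  # receptor-ligand cross LJ
  lj <- lj_pair_terms(rc, lc, ff$sig_cross, ff$eps_cross)
  breakdown[1L] <- lj$energy
  g <- lj$dEdr_over_r
  # force on receptor atom a = -sum_l g[a,l] (rc[a,] - lc[l,]); ligand mirrors
  forces[ri, ] <- forces[ri, ] - (rc * .rowSums(g, nrow(g), ncol(g)) - g %*% lc)
  forces[li, ] <- forces[li, ] - (lc * .colSums(g, nrow(g), ncol(g)) - crossprod(g, rc))

  # intra-ligand non-bonded LJ
  if (length(ff$lp_i) > 0L) {
    i <- ff$lp_i
    j <- ff$lp_j
    dv <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    d2 <- pmax(dv[, 1L]^2 + dv[, 2L]^2 + dv[, 3L]^2, 1e-12)
    inv6 <- (ff$lp_sig^2 / d2)^3
    breakdown[2L] <- sum(4 * ff$lp_eps * (inv6^2 - inv6))
    gv <- 4 * ff$lp_eps * (-12 * inv6^2 + 6 * inv6) / d2
    fv <- -gv * dv
    forces <- forces + accumulate_pair_forces(n, i, j, fv)
  }

  # harmonic bonds E = k (r - r0)^2
  if (length(ff$b_i) > 0L) {
    i <- ff$b_i
    j <- ff$b_j
    dv <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    d <- sqrt(dv[, 1L]^2 + dv[, 2L]^2 + dv[, 3L]^2)
    breakdown[3L] <- sum(ff$b_k * (d - ff$b_r0)^2)
    fv <- (-2 * ff$b_k * (d - ff$b_r0) / d) * dv
    forces <- forces + accumulate_pair_forces(n, i, j, fv)
  }

  if (!is.null(restraints)) {
    if (length(restraints$p_i) > 0L) {
      i <- restraints$p_i
      dv <- coords[i, , drop = FALSE] - restraints$p_ref
      breakdown[4L] <- sum(restraints$p_k * (dv[, 1L]^2 + dv[, 2L]^2 + dv[, 3L]^2))
      fp <- -2 * restraints$p_k * dv
      if (anyDuplicated(i)) {
        for (k in seq_along(i)) forces[i[k], ] <- forces[i[k], ] + fp[k, ]
      } else {
        forces[i, ] <- forces[i, ] + fp
      }
    }
    if (length(restraints$q_i) > 0L) {
      i <- restraints$q_i
      j <- restraints$q_j
      dv <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
      d <- sqrt(pmax(dv[, 1L]^2 + dv[, 2L]^2 + dv[, 3L]^2, 1e-12))
      breakdown[5L] <- sum(restraints$q_k * (d - restraints$q_r)^2)
      fv <- (-2 * restraints$q_k * (d - restraints$q_r) / d) * dv
      forces <- forces + accumulate_pair_forces(n, i, j, fv)
    }
  }

  bias_diag <- NULL
  if (!is.null(bias)) {
    bd <- bias(coords)
    if (isTRUE(bd$guard_active)) {
      breakdown[7L] <- bd$energy
    } else {
      breakdown[6L] <- bd$energy
    }
    forces <- forces + bd$forces
    bias_diag <- list(
      d_ave12 = bd$d_ave12, n_pairs = bd$n_pairs,
      guard_active = bd$guard_active
    )
  }

  total <- sum(breakdown)
  if (!is.finite(total)) {
    bad <- names(breakdown)[!is.finite(breakdown)]
    stop(sprintf("non-finite energy in term(s): %s", paste(bad, collapse = ", ")))
  }
  list(energy = total, forces = forces, breakdown = breakdown, bias_diag = bias_diag)
}

# scatter-add pair forces (+f on i, -f on j), robust to duplicate indices
accumulate_pair_forces <- function(n, i, j, fv) {
  out <- matrix(0, n, 3L)
  for (k in seq_along(i)) {
    out[i[k], ] <- out[i[k], ] + fv[k, ]
    out[j[k], ] <- out[j[k], ] - fv[k, ]
  }
  out
}

#' Receptor-ligand nonbonded interaction energy
#'
#' Cross Lennard-Jones terms only (no intra-partner energy, no bias, guard or
#' restraints), evaluated with no cutoff.
#'
#' @inheritParams compute_energy_forces
#' @return energy in kcal/mol.
#' @export
interaction_energy <- function(system, ff, coords) {
  coords <- as_coord_matrix(coords)
  rc <- coords[ff$receptor_idx, , drop = FALSE]
  lc <- coords[ff$ligand_idx, , drop = FALSE]
  lj_pair_terms(rc, lc, ff$sig_cross, ff$eps_cross)$energy
}

# --- RNG streams -----------------------------------------------------------
# Each simulation state carries its own R RNG state so replicas evolve on
# independent, reproducible streams derived from one master seed.

derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + index) %% 2147483647)
}

new_rng_stream <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
  s
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream, globalenv())
  value <- force(expr)
  new_stream <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
  list(value = value, stream = new_stream)
}

#' Create a simulation state
#'
#' @param coords N x 3 starting frame (Angstrom).
#' @param masses per-atom masses (amu).
#' @param temperature target temperature (K).
#' @param seed integer seed for this state's private RNG stream.
#' @param velocities optional N x 3 matrix (Angstrom/ps); when NULL, drawn
#'   from the Maxwell-Boltzmann distribution at `temperature`.
#' @param frozen optional N x 3 logical matrix (or per-atom logical vector)
#'   of immobilised degrees of freedom.
#' @return An object of class `SimulationState`.
#' @export
sim_state <- function(coords, masses, temperature = 300, seed = 1,
                      velocities = NULL, frozen = NULL) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (length(masses) != n) stop("masses length must match atom count")
  if (temperature <= 0) stop("temperature must be positive")
  if (is.null(frozen)) {
    frozen <- matrix(FALSE, n, 3L)
  } else if (is.vector(frozen)) {
    frozen <- matrix(frozen, n, 3L)
  }
  stream <- new_rng_stream(seed)
  if (is.null(velocities)) {
    sd_v <- sqrt(KB_KCAL * temperature * AKMA / masses)
    r <- with_stream(stream, matrix(stats::rnorm(3 * n), n, 3L))
    stream <- r$stream
    velocities <- r$value * sd_v
  }
  velocities[frozen] <- 0
  structure(
    list(
      coords = coords, velocities = velocities, masses = masses,
      temperature = temperature, step = 0L, rng_stream = stream,
      frozen = frozen, forces = NULL
    ),
    class = "SimulationState"
  )
}

#' One BAOAB Langevin step
#'
#' Splitting B (half kick) - A (half drift) - O (Ornstein-Uhlenbeck velocity
#' update) - A (half drift) - B (half kick with re-evaluated forces). With
#' gamma = 0 the scheme reduces to velocity Verlet and conserves energy in
#' the small-step limit; the trajectory is deterministic given the state's
#' RNG stream.
#'
#' @param state a `SimulationState`.
#' @param force_fn closure `function(coords)` returning at least
#'   list(energy, forces).
#' @param dt time step (ps).
#' @param gamma collision frequency (ps^-1, default 0.1).
#' @return updated `SimulationState` (with cached `forces` and `energy`).
#' @export
langevin_step <- function(state, force_fn, dt, gamma = 0.1) {
  out <- run_segment(state, force_fn, 1L, dt, gamma, record_every = 0)
  out$state
}

# raw BAOAB update; consumes the active .Random.seed when gamma > 0
baoab_step_raw <- function(x, v, f, force_fn, frozen, any_frozen,
                           a_scale, dt_half, c1, c2, sd_v) {
  v <- v + f * a_scale
  x1 <- x + v * dt_half
  if (!is.null(c1)) {
    v <- c1 * v + c2 * sd_v * matrix(stats::rnorm(length(v)), nrow(v), 3L)
  }
  x1 <- x1 + v * dt_half
  if (any_frozen) x1[frozen] <- x[frozen]
  ev <- force_fn(x1)
  v <- v + ev$forces * a_scale
  if (any_frozen) v[frozen] <- 0
  list(x = x1, v = v, ev = ev)
}

#' Run a segment of Langevin dynamics
#'
#' BAOAB steps with one force evaluation per step (the closing half-kick
#' force is reused as the opening half-kick of the next step). Frames and
#' energy records are taken every `record_every` steps; trajectories are
#' bit-reproducible for a fixed state RNG stream.
#'
#' @param state a `SimulationState`.
#' @param force_fn closure as in [langevin_step()].
#' @param n_steps number of steps (>= 1).
#' @param dt time step (ps).
#' @param gamma collision frequency (ps^-1).
#' @param record_every record a frame every this many steps (0 = no frames).
#' @return list(state, frames, records) where records is a data.frame with
#'   step, energy and the per-term breakdown at the recorded steps.
#' @export
run_segment <- function(state, force_fn, n_steps, dt, gamma = 0.1,
                        record_every = 0) {
  stopifnot(n_steps >= 1)
  if (dt <= 0) stop("dt must be positive")
  if (gamma < 0) stop("gamma must be >= 0")
  m <- state$masses
  frozen <- state$frozen
  any_frozen <- any(frozen)
  a_scale <- dt / 2 * AKMA / m
  dt_half <- dt / 2
  if (gamma > 0) {
    c1 <- exp(-gamma * dt)
    c2 <- sqrt(1 - c1^2)
    sd_v <- sqrt(KB_KCAL * state$temperature * AKMA / m)
  } else {
    c1 <- NULL
    c2 <- NULL
    sd_v <- NULL
  }
  if (is.null(state$forces)) {
    state$forces <- force_fn(state$coords)$forces
  }
  x <- state$coords
  v <- state$velocities
  f <- state$forces

  # activate this state's private RNG stream for the whole segment
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state$rng_stream, globalenv())
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })

  n_rec <- if (record_every > 0) n_steps %/% record_every else 0L
  frames <- if (n_rec > 0L) vector("list", n_rec) else list()
  rec <- if (n_rec > 0L) matrix(NA_real_, n_rec, 12L) else NULL
  ridx <- 0L
  ev <- NULL
  for (s in seq_len(n_steps)) {
    up <- baoab_step_raw(
      x, v, f, force_fn, frozen, any_frozen,
      a_scale, dt_half, c1, c2, sd_v
    )
    x <- up$x
    v <- up$v
    f <- up$ev$forces
    ev <- up$ev
    if (record_every > 0 && s %% record_every == 0L) {
      ridx <- ridx + 1L
      frames[[ridx]] <- x
      bd <- ev$bias_diag
      rec[ridx, ] <- c(
        state$step + s, ev$energy, ev$breakdown,
        if (is.null(bd)) c(NA_real_, NA_real_, NA_real_) else {
          c(
            if (is.null(bd$d_ave12)) NA_real_ else bd$d_ave12,
            bd$n_pairs, as.numeric(bd$guard_active)
          )
        }
      )
    }
  }
  state$rng_stream <- get(".Random.seed", globalenv())
  state$coords <- x
  state$velocities <- v
  state$forces <- f
  state$energy <- if (!is.null(ev)) ev$energy else NA_real_
  state$last_eval <- ev
  state$step <- state$step + n_steps
  records <- NULL
  if (ridx > 0L) {
    records <- data.frame(
      step = as.integer(rec[, 1L]), energy = rec[, 2L],
      pair = rec[, 3L], ligand_pair = rec[, 4L], bond = rec[, 5L],
      positional = rec[, 6L], pair_distance = rec[, 7L],
      bias = rec[, 8L], guard = rec[, 9L],
      d_ave12 = rec[, 10L], n_pairs = as.integer(rec[, 11L]),
      guard_active = !is.na(rec[, 12L]) & rec[, 12L] > 0
    )
    if (is.null(ev$bias_diag)) {
      records$d_ave12 <- NULL
      records$n_pairs <- NULL
      records$guard_active <- NULL
    }
  }
  list(state = state, frames = frames, records = records)
}

#' Kinetic energy of a state (kcal/mol)
#' @param state a `SimulationState`.
#' @return kinetic energy in kcal/mol.
#' @export
kinetic_energy <- function(state) {
  sum(state$masses * rowSums(state$velocities^2)) / (2 * AKMA)
}

#' Instantaneous kinetic temperature (K)
#'
#' Uses the number of unfrozen degrees of freedom.
#' @param state a `SimulationState`.
#' @return temperature estimate in K.
#' @export
kinetic_temperature <- function(state) {
  ndof <- sum(!state$frozen)
  2 * kinetic_energy(state) / (ndof * KB_KCAL)
}
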