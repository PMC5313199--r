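# Synthetic fixtures: sticky-surface docking systems with a certified native
# site, an analytic harmonic pair system for detailed-balance checks, and
# mini PDB fixtures for I/O tests.

# farthest-point selection of n_sites indices among unit direction vectors
spread_sites <- function(dirs, n_sites, first) {
  chosen <- first
  while (length(chosen) < n_sites) {
    dmin <- apply(dirs %*% t(dirs[chosen, , drop = FALSE]), 1L, max)
    dmin[chosen] <- Inf # cosine similarity; pick the most dissimilar point
    cand <- which.min(dmin)
    chosen <- c(chosen, cand)
  }
  chosen
}

#' Build a sticky-receptor toy docking system
#'
#' Receptor beads sit on a convex spherical shell (Fibonacci lattice) and are
#' positionally restrained (k = 0.5 kcal mol^-1 A^-2); the ligand is a short
#' bonded bead chain. One receptor bead is the native site (deepest
#' cross-interaction well) and `n_decoys` beads are shallower sticky decoys,
#' all maximally spread over the shell; the starting pose places the ligand
#' antipodal to the native site. A rigid grid scan over ligand placements
#' certifies that the native pose is the global minimum of the
#' receptor-ligand interaction; the certificate is stored in the metadata.
#'
#' @param n_receptor_beads shell size (default 32).
#' @param n_ligand_beads ligand chain length (default 1: the benchmark
#'   measures binding-site search, so the default ligand is a single bead;
#'   longer bonded chains are fully supported).
#' @param n_decoys number of sticky decoy sites (>= 1, default 4).
#' @param native_depth native-site well depth in kcal/mol (default 12).
#' @param decoy_depth decoy well depth in kcal/mol (default 4.8, keeping the
#'   native:decoy ratio at 2.5:1; must be smaller than `native_depth`).
#' @param base_epsilon nonspecific surface well depth (default 0.3).
#' @param sigma bead LJ diameter in Angstrom (default 2).
#' @param shell_radius receptor shell radius in Angstrom (default 6).
#' @param seed integer seed recorded in the metadata (the construction is
#'   deterministic; the seed is the default for downstream dynamics).
#' @param grid_n number of scan directions for the certificate (default 1000).
#' @return An object of class `ToyDockingSystem`: list(system, ff, restraints,
#'   groups_hint, native_pose, start_pose, metadata).
#' @export
make_sticky_receptor <- function(n_receptor_beads = 32, n_ligand_beads = 1,
                                 n_decoys = 4, native_depth = 12.0,
                                 decoy_depth = 4.8, base_epsilon = 0.3,
                                 sigma = 2.0, shell_radius = 6.0, seed = 1,
                                 grid_n = 1000) {
  if (!(native_depth > decoy_depth && decoy_depth > 0)) {
    stop("require native_depth > decoy_depth > 0")
  }
  if (n_decoys < 1) stop("n_decoys must be >= 1")
  if (n_decoys + 1 > n_receptor_beads / 2) {
    stop("too many sites for the shell: minimum angular separation not achievable")
  }
  dirs <- fibonacci_sphere(n_receptor_beads)
  rec <- dirs * shell_radius
  # native site: bead closest to +z; decoys spread maximally away from it
  native_bead <- which.max(dirs[, 3L])
  sites <- spread_sites(dirs, n_decoys + 1L, native_bead)
  decoy_beads <- sites[-1L]

  contact_r <- shell_radius + sigma * 2^(1 / 6)
  lig_axis <- function(u) {
    # unit vector tangent to the shell at direction u
    ref <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- ref - sum(ref * u) * u
    t1 / sqrt(sum(t1^2))
  }
  place_ligand <- function(u, r = contact_r) {
    center <- u * r
    ax <- lig_axis(u)
    offs <- (seq_len(n_ligand_beads) - (n_ligand_beads + 1) / 2) * sigma
    sweep(outer(offs, ax), 2L, center, `+`)
  }
  native_dir <- dirs[native_bead, ]
  native_lig <- place_ligand(native_dir)
  start_dir <- -native_dir
  start_lig <- place_ligand(start_dir)

  n_total <- n_receptor_beads + n_ligand_beads
  atoms <- data.frame(
    serial = seq_len(n_total),
    name = sprintf("B%d", seq_len(n_total)),
    resname = c(rep("REC", n_receptor_beads), rep("LIG", n_ligand_beads)),
    chain = c(rep("A", n_receptor_beads), rep("B", n_ligand_beads)),
    resid = c(seq_len(n_receptor_beads), rep(1L, n_ligand_beads)),
    element = "X",
    radius = sigma / 2,
    mass = 12.0,
    stringsAsFactors = FALSE
  )
  coords <- rbind(rec, start_lig)
  system <- molecular_system(atoms, coords,
    receptor_idx = seq_len(n_receptor_beads),
    ligand_idx = n_receptor_beads + seq_len(n_ligand_beads)
  )

  site_depth <- rep(NA_real_, n_receptor_beads)
  site_depth[decoy_beads] <- decoy_depth
  site_depth[native_bead] <- native_depth
  lig_idx <- system$ligand_idx
  bonds <- if (n_ligand_beads > 1L) {
    data.frame(
      i = lig_idx[-n_ligand_beads], j = lig_idx[-1L],
      r0 = sigma, k = 25
    )
  } else {
    NULL
  }
  ff <- toy_forcefield(system,
    sigma = sigma, epsilon = base_epsilon,
    site_depth = site_depth, bonds = bonds
  )
  restraints <- restraint_set(
    positional = data.frame(
      i = seq_len(n_receptor_beads),
      x = rec[, 1L], y = rec[, 2L], z = rec[, 3L], k = 0.5
    )
  )

  # grid-scan certificate: rigid ligand over grid_n shell directions
  scan_dirs <- fibonacci_sphere(grid_n)
  scan_e <- apply(scan_dirs, 1L, function(u) {
    interaction_energy(system, ff, rbind(rec, place_ligand(u)))
  })
  best <- which.min(scan_e)
  best_center <- scan_dirs[best, ] * contact_r
  native_center <- native_dir * contact_r
  dist_to_native <- sqrt(sum((best_center - native_center)^2))
  certified <- dist_to_native <= sigma / 2 # within 1 bead radius
  if (!certified) {
    stop(sprintf(
      "native pose is not the grid-scan global minimum (off by %.2f A)",
      dist_to_native
    ))
  }
  native_pose <- rbind(rec, native_lig)

  structure(
    list(
      system = system, ff = ff, restraints = restraints,
      native_pose = native_pose, start_pose = coords,
      native_bead = native_bead, decoy_beads = decoy_beads,
      metadata = list(
        seed = seed, native_depth = native_depth, decoy_depth = decoy_depth,
        base_epsilon = base_epsilon, sigma = sigma,
        shell_radius = shell_radius, grid_n = grid_n,
        grid_min_energy = scan_e[best], grid_min_dist_to_native = dist_to_native,
        certified = certified
      )
    ),
    class = "ToyDockingSystem"
  )
}

#' Harmonic pair system with analytic stationary densities
#'
#' One frozen bead at the origin plus one mobile bead restricted to the
#' x axis, with base potential U(d) = 1/2 k_base (d - x0)^2 in the
#' separation coordinate (realised through the engine's bond term). Both
#' beads form the surface groups, so the separation equals the weighted mean
#' distance whenever it is within the contact cutoff. The returned `density`
#' closure gives the exact normalised Boltzmann density of the separation
#' under any bias window (1-D trapezoid quadrature), including the
#' dissociation guard beyond the cutoff.
#'
#' @param k_base base spring constant, kcal mol^-1 A^-2.
#' @param x0 rest separation (Angstrom).
#' @param temperature temperature (K, default 300).
#' @param cutoff contact cutoff (default 10).
#' @param mass mobile bead mass (amu, default 12).
#' @return list(system, ff, restraints, groups, frozen, density,
#'   k_base, x0, ...).
#' @export
make_harmonic_pair_system <- function(k_base, x0, temperature = 300,
                                      cutoff = 10, mass = 12) {
  if (k_base <= 0) stop("k_base must be positive")
  atoms <- data.frame(
    serial = 1:2, name = c("B1", "B2"), resname = c("REC", "LIG"),
    chain = c("A", "B"), resid = c(1L, 1L), element = "X",
    radius = 1.0, mass = mass, stringsAsFactors = FALSE
  )
  coords <- rbind(c(0, 0, 0), c(x0, 0, 0))
  system <- molecular_system(atoms, coords, receptor_idx = 1L, ligand_idx = 2L)
  ff <- toy_forcefield(system,
    sigma = 1, epsilon = 0, # no LJ: pure harmonic base potential
    bonds = data.frame(i = 1L, j = 2L, r0 = x0, k = k_base / 2)
  )
  restraints <- restraint_set()
  groups <- structure(
    list(
      receptor_atoms = 1L, ligand_atoms = 2L,
      area = c(NA_real_, NA_real_), min_area = 0, probe = 1.5
    ),
    class = "SurfaceGroups"
  )
  frozen <- rbind(c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE))
  kT <- KB_KCAL * temperature

  density <- function(window = NULL, guard_k = if (is.null(window)) 2.5 else window$k_f,
                      grid = seq(0.05, 15, by = 0.001)) {
    u <- 0.5 * k_base * (grid - x0)^2
    if (!is.null(window)) {
      inside <- grid < cutoff
      h <- ifelse(
        grid <= window$d_low, window$k_f * (grid - window$d_low)^2,
        ifelse(grid >= window$d_up, window$k_f * (grid - window$d_up)^2, 0)
      )
      u <- u + ifelse(inside, h, guard_k * (grid - cutoff)^2)
    } else {
      u <- u + ifelse(grid < cutoff, 0, guard_k * (grid - cutoff)^2)
    }
    w <- exp(-(u - min(u)) / kT)
    z <- sum((w[-1L] + w[-length(w)]) / 2 * diff(grid))
    list(x = grid, density = w / z)
  }

  list(
    system = system, ff = ff, restraints = restraints, groups = groups,
    frozen = frozen, density = density, k_base = k_base, x0 = x0,
    temperature = temperature, cutoff = cutoff
  )
}

#' Generate a small two-chain PDB fixture
#'
#' @param n_atoms_per_chain atoms per chain (>= 3).
#' @param seed integer seed.
#' @return character scalar: the PDB text (with coordinates as attribute
#'   `coords` and chain labels as attribute `chains`).
#' @export
make_mini_pdb_fixture <- function(n_atoms_per_chain = 3, seed = 1) {
  if (n_atoms_per_chain < 3) stop("need at least 3 atoms per chain")
  r <- with_stream(
    new_rng_stream(seed),
    matrix(stats::runif(6 * n_atoms_per_chain, -20, 20), ncol = 3L)
  )
  coords <- round(r$value, 3L)
  n <- 2L * n_atoms_per_chain
  chains <- rep(c("A", "B"), each = n_atoms_per_chain)
  elements <- rep(c("C", "N", "O"), length.out = n)
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), paste0(elements, "A"), "GLY", chains,
    rep(seq_len(n_atoms_per_chain), 2L),
    coords[, 1L], coords[, 2L], coords[, 3L], 1, 0, elements
  )
  text <- paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
  attr(text, "coords") <- coords
  attr(text, "chains") <- chains
  text
}
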