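# Run configuration, orchestration entry points and reproducibility
# manifests. Config files are flat YAML key groups mirroring the module
# defaults (surface.*, bias.*, engine.*, remd.*, toy.*, analysis.*).

#' Default toy-scale replica ladder
#'
#' Four overlapping windows calibrated for the bead systems (contact
#' d_ave-12 around 2.2-2.5 Angstrom for sigma = 2 beads): the reference
#' window opens at 2 Angstrom so bound poses score zero bias, and the upper
#' windows push the ligand progressively off the surface.
#'
#' @param k_f force constant applied to every window (default 2.5).
#' @return A `ReplicaLadder` with 4 windows.
#' @export
toy_ladder <- function(k_f = 2.5) {
  replica_ladder(list(
    bias_window(2.0, 4.0, k_f),
    bias_window(3.2, 5.2, k_f),
    bias_window(4.0, 6.0, k_f),
    bias_window(4.6, 6.7, k_f)
  ))
}

#' Default run configuration
#'
#' All defaults follow the published protocol where one exists (k_f 2.5,
#' contact cutoff 10 A, probe 1.5 A, min area 10 A^2, 300 K, collision
#' frequency 0.1 ps^-1); the remaining values are documented package
#' choices for the desk-scale toy systems.
#'
#' @return nested list of parameter groups.
#' @export
default_run_config <- function() {
  list(
    surface = list(min_area = 10, probe = 1.5, cutoff = 10, n_sphere_points = 960),
    bias = list(exponent = 12, k_f = 2.5, ladder = "toy4", normalization = "restricted"),
    engine = list(dt = 0.005, gamma = 0.1, temperature = 300, seed = 1),
    remd = list(n_steps = 6000, exchange_interval = 20, record_every = 10),
    toy = list(
      n_receptor_beads = 32, n_ligand_beads = 1, n_decoys = 4,
      native_depth = 12.0, decoy_depth = 4.8, base_epsilon = 0.3,
      sigma = 2.0, shell_radius = 6.0
    ),
    analysis = list(thresholds = c(2, 4), cluster_radius = 4)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()]; unknown keys
#' raise an error before any computation.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return validated config list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (grp in names(user)) {
      if (!grp %in% names(cfg)) stop(sprintf("unknown config group '%s'", grp))
      for (key in names(user[[grp]])) {
        if (!key %in% names(cfg[[grp]])) {
          stop(sprintf("unknown config key '%s.%s'", grp, key))
        }
        cfg[[grp]][[key]] <- user[[grp]][[key]]
      }
    }
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks every parameter group against its documented range; called by all
#' pipeline entry points before any computation.
#'
#' @param cfg config list as from [default_run_config()].
#' @return the validated config, invisibly unchanged.
#' @export
validate_run_config <- function(cfg) {
  s <- cfg$surface
  stopifnot(s$min_area >= 0, s$probe > 0, s$cutoff > 0, s$n_sphere_points >= 92)
  b <- cfg$bias
  if (!b$exponent %in% c(6, 12)) stop("bias.exponent must be 6 or 12")
  if (b$k_f < 0) stop("bias.k_f must be >= 0")
  if (!b$normalization %in% c("restricted", "full")) {
    stop("bias.normalization must be 'restricted' or 'full'")
  }
  if (is.null(b$ladder)) stop("missing config key 'bias.ladder'")
  e <- cfg$engine
  stopifnot(e$dt > 0, e$gamma >= 0, e$temperature > 0)
  r <- cfg$remd
  stopifnot(r$n_steps >= 1, r$exchange_interval >= 1, r$record_every >= 0)
  cfg
}

#' Resolve a ladder specification
#'
#' @param spec "toy4", "ladder6", "ladder10", "ladder12", a `ReplicaLadder`,
#'   or a list of (d_low, d_up) pairs.
#' @param k_f force constant for windows built from bare bounds.
#' @return A `ReplicaLadder`.
#' @export
resolve_ladder <- function(spec, k_f = 2.5) {
  if (inherits(spec, "ReplicaLadder")) {
    return(spec)
  }
  if (is.character(spec) && length(spec) == 1L) {
    if (spec == "toy4") {
      return(toy_ladder(k_f))
    }
    return(ladder_preset(spec, k_f))
  }
  if (is.list(spec)) {
    return(replica_ladder(lapply(spec, function(b) {
      bias_window(b[[1L]], b[[2L]], if (length(b) >= 3L) b[[3L]] else k_f)
    })))
  }
  stop("unrecognized ladder specification")
}

write_manifest <- function(path, cfg, extra = list()) {
  manifest <- c(
    list(
      package = "bpremd",
      version = as.character(utils::packageVersion("bpremd")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      created = "run-manifest",
      config = cfg
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_csv_exact <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Run the full docking protocol on a toy system
#'
#' Surface selection, ladder construction, replica-exchange run and analysis
#' in one call: writes per-replica XYZ trajectories, the exchange log, the
#' per-frame diagnostics, the near-native fractions table, the cluster table
#' and a JSON manifest sufficient to reproduce the run bitwise.
#'
#' @param config a config list (see [default_run_config()]) or a YAML path.
#' @param out_dir output directory (created if needed).
#' @param toy optional pre-built `ToyDockingSystem`; by default one is
#'   generated from the `toy` config group.
#' @return invisibly, list(out_dir, store, rmsd_ref, fractions, clusters).
#' @export
run_docking <- function(config = default_run_config(), out_dir, toy = NULL) {
  cfg <- if (is.character(config)) load_run_config(config) else validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$engine$seed
  if (is.null(toy)) {
    toy <- do.call(make_sticky_receptor, c(cfg$toy, list(seed = seed)))
  }
  system <- toy$system
  groups <- select_surface_atoms(system,
    min_area = cfg$surface$min_area,
    probe = cfg$surface$probe,
    n_sphere_points = cfg$surface$n_sphere_points
  )
  ladder <- resolve_ladder(cfg$bias$ladder, cfg$bias$k_f)
  store <- run_hremd(system, toy$ff, toy$restraints, groups, ladder,
    n_steps = cfg$remd$n_steps,
    exchange_interval = cfg$remd$exchange_interval,
    seed = seed,
    dt = cfg$engine$dt, gamma = cfg$engine$gamma,
    temperature = cfg$engine$temperature,
    record_every = cfg$remd$record_every,
    cutoff = cfg$surface$cutoff,
    exponent = cfg$bias$exponent,
    normalization = cfg$bias$normalization
  )

  for (i in seq_len(store$n_replicas)) {
    write_xyz_trajectory(store, i, file.path(out_dir, sprintf("replica_%02d.xyz", i)))
  }
  write_csv_exact(store$exchanges, file.path(out_dir, "exchange_log.csv"))
  write_csv_exact(store$diagnostics, file.path(out_dir, "diagnostics.csv"))
  write_pdb(system, file.path(out_dir, "reference.pdb"), coords = toy$native_pose)

  an <- analyze_store(store, toy, cfg)
  write_csv_exact(an$fractions, file.path(out_dir, "fractions.csv"))
  write_csv_exact(an$clusters, file.path(out_dir, "clusters.csv"))
  write_csv_exact(an$rmsd, file.path(out_dir, "rmsd.csv"))

  write_manifest(file.path(out_dir, "manifest.json"), cfg,
    extra = list(seed = seed, toy_metadata = toy$metadata)
  )
  invisible(list(
    out_dir = out_dir, store = store,
    fractions = an$fractions, clusters = an$clusters, rmsd = an$rmsd
  ))
}

analyze_store <- function(store, toy, cfg) {
  system <- toy$system
  rsel <- system$receptor_idx
  lsel <- system$ligand_idx
  thr <- sort(cfg$analysis$thresholds)
  rows <- list()
  rmsd_rows <- list()
  for (i in seq_len(store$n_replicas)) {
    series <- ligand_rmsd_series(store$frames[[i]], toy$native_pose, rsel, lsel)
    n <- length(series)
    halves <- list(first_half = seq_len(floor(n / 2)), second_half = (floor(n / 2) + 1L):n)
    row <- data.frame(replica = i)
    for (h in names(halves)) {
      for (t in thr) {
        row[[sprintf("%s_lt%g", h, t)]] <- near_native_fraction(series, t, halves[[h]])
      }
    }
    rows[[i]] <- row
    rmsd_rows[[i]] <- data.frame(
      replica = i,
      step = store$diagnostics$step[store$diagnostics$replica == i][seq_len(n)],
      rmsd = series
    )
  }
  cl <- leader_cluster(store$frames[[1L]], toy$native_pose, rsel, lsel,
    radius = cfg$analysis$cluster_radius
  )
  list(
    fractions = do.call(rbind, rows),
    clusters = cl$sizes,
    rmsd = do.call(rbind, rmsd_rows)
  )
}

#' Analyze stored trajectories against a reference pose
#'
#' Standalone analysis pass over XYZ trajectories written by [run_docking()]:
#' recomputes the RMSD series, the near-native fraction table (half-run
#' windows at the configured thresholds) and the cluster table.
#'
#' @param trajectory_paths character vector of XYZ paths (one per replica).
#' @param reference_pdb PDB path of the native complex (chain split as in
#'   the trajectories).
#' @param config config list or YAML path.
#' @param out_dir optional output directory for the CSV tables.
#' @return list(rmsd, fractions, clusters).
#' @export
analyze_trajectories <- function(trajectory_paths, reference_pdb,
                                 config = default_run_config(), out_dir = NULL) {
  cfg <- if (is.character(config)) load_run_config(config) else validate_run_config(config)
  ref_sys <- read_pdb(reference_pdb)
  rsel <- ref_sys$receptor_idx
  lsel <- ref_sys$ligand_idx
  thr <- sort(cfg$analysis$thresholds)
  rows <- list()
  rmsd_rows <- list()
  all_first <- NULL
  for (i in seq_along(trajectory_paths)) {
    tr <- read_xyz_trajectory(trajectory_paths[[i]])
    if (length(tr$frames) == 0L) stop("empty trajectory: ", trajectory_paths[[i]])
    if (nrow(tr$frames[[1L]]) != n_atoms(ref_sys)) {
      stop("atom count mismatch between trajectory and reference")
    }
    series <- ligand_rmsd_series(tr$frames, ref_sys$coords, rsel, lsel)
    n <- length(series)
    halves <- list(first_half = seq_len(floor(n / 2)), second_half = (floor(n / 2) + 1L):n)
    row <- data.frame(trajectory = basename(trajectory_paths[[i]]))
    for (h in names(halves)) {
      for (t in thr) {
        row[[sprintf("%s_lt%g", h, t)]] <- near_native_fraction(series, t, halves[[h]])
      }
    }
    rows[[i]] <- row
    rmsd_rows[[i]] <- data.frame(trajectory = row$trajectory, frame = seq_len(n), rmsd = series)
    if (i == 1L) all_first <- tr$frames
  }
  cl <- leader_cluster(all_first, ref_sys$coords, rsel, lsel,
    radius = cfg$analysis$cluster_radius
  )
  out <- list(
    rmsd = do.call(rbind, rmsd_rows),
    fractions = do.call(rbind, rows),
    clusters = cl$sizes
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_exact(out$fractions, file.path(out_dir, "fractions.csv"))
    write_csv_exact(out$clusters, file.path(out_dir, "clusters.csv"))
    write_csv_exact(out$rmsd, file.path(out_dir, "rmsd.csv"))
  }
  out
}

#' Benchmark replica exchange against matched-cost conventional dynamics
#'
#' On the certified sticky-receptor system, runs for each seed (a) the
#' replica-exchange protocol and (b) a single-replica conventional arm under
#' the reference-replica Hamiltonian with the same total step budget
#' (n_replicas x n_steps). Success means the reference-replica ligand RMSD
#' drops below one bead diameter before the budget is exhausted.
#'
#' @param config config list or YAML path.
#' @param seeds integer vector of run seeds (>= 5 recommended).
#' @param out_dir optional directory for the report CSV/JSON.
#' @return list(report, summary): per-seed table and aggregate counts /
#'   median first-passage steps (Inf when an arm never succeeds).
#' @export
run_benchmark <- function(config = default_run_config(), seeds = 1:10, out_dir = NULL) {
  cfg <- if (is.character(config)) load_run_config(config) else validate_run_config(config)
  ladder <- resolve_ladder(cfg$bias$ladder, cfg$bias$k_f)
  n_rep <- length(ladder$windows)
  threshold <- cfg$toy$sigma # one bead diameter
  rows <- list()
  for (seed in seeds) {
    toy <- do.call(make_sticky_receptor, c(cfg$toy, list(seed = seed)))
    system <- toy$system
    groups <- select_surface_atoms(system,
      min_area = cfg$surface$min_area, probe = cfg$surface$probe,
      n_sphere_points = cfg$surface$n_sphere_points
    )
    common <- list(
      system = system, ff = toy$ff, restraints = toy$restraints,
      groups = groups,
      exchange_interval = cfg$remd$exchange_interval,
      dt = cfg$engine$dt, gamma = cfg$engine$gamma,
      temperature = cfg$engine$temperature,
      record_every = cfg$remd$record_every,
      cutoff = cfg$surface$cutoff, exponent = cfg$bias$exponent,
      normalization = cfg$bias$normalization
    )
    remd <- do.call(run_hremd, c(common, list(
      ladder = ladder, n_steps = cfg$remd$n_steps, seed = seed
    )))
    cmd <- do.call(run_hremd, c(common, list(
      ladder = replica_ladder(ladder$windows[1L]),
      n_steps = cfg$remd$n_steps * n_rep, seed = seed
    )))
    rsel <- system$receptor_idx
    lsel <- system$ligand_idx
    remd_series <- ligand_rmsd_series(remd$frames[[1L]], toy$native_pose, rsel, lsel)
    cmd_series <- ligand_rmsd_series(cmd$frames[[1L]], toy$native_pose, rsel, lsel)
    # first passage in engine steps; REMD reference replica frames cover
    # n_steps, the cMD arm covers n_rep * n_steps with the same stride
    fp_remd <- first_passage(remd_series, threshold)
    fp_cmd <- first_passage(cmd_series, threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed,
      total_steps_remd = cfg$remd$n_steps * n_rep,
      total_steps_cmd = cfg$remd$n_steps * n_rep,
      remd_success = !is.na(fp_remd),
      cmd_success = !is.na(fp_cmd),
      remd_first_passage_step = ifelse(is.na(fp_remd), NA,
        fp_remd * cfg$remd$record_every
      ),
      cmd_first_passage_step = ifelse(is.na(fp_cmd), NA,
        fp_cmd * cfg$remd$record_every
      ),
      remd_frac_lt2 = near_native_fraction(remd_series, 2),
      remd_frac_lt4 = near_native_fraction(remd_series, 4),
      cmd_frac_lt2 = near_native_fraction(cmd_series, 2),
      cmd_frac_lt4 = near_native_fraction(cmd_series, 4)
    )
  }
  report <- do.call(rbind, rows)
  med <- function(x) {
    x[is.na(x)] <- Inf
    stats::median(x)
  }
  summary <- list(
    seeds = seeds,
    threshold = threshold,
    total_steps_per_arm = cfg$remd$n_steps * n_rep,
    remd_successes = sum(report$remd_success),
    cmd_successes = sum(report$cmd_success),
    remd_median_first_passage = med(report$remd_first_passage_step),
    cmd_median_first_passage = med(report$cmd_first_passage_step)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_exact(report, file.path(out_dir, "benchmark_report.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "benchmark_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(report = report, summary = summary)
}

#' Write a toy docking system to disk
#'
#' Emits the start-pose PDB, the native reference PDB and a JSON description
#' of the force field and metadata.
#'
#' @param config config list or YAML path (the `toy` group is used).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return invisibly, the `ToyDockingSystem`.
#' @export
make_toy_files <- function(config = default_run_config(), out_dir, seed = 1) {
  cfg <- if (is.character(config)) load_run_config(config) else validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  toy <- do.call(make_sticky_receptor, c(cfg$toy, list(seed = seed)))
  write_pdb(toy$system, file.path(out_dir, "start.pdb"))
  write_pdb(toy$system, file.path(out_dir, "native.pdb"), coords = toy$native_pose)
  ff_desc <- list(
    sigma = toy$ff$sigma, epsilon = toy$ff$epsilon,
    site_depth = toy$ff$site_depth, bonds = toy$ff$bonds,
    native_bead = toy$native_bead, decoy_beads = toy$decoy_beads,
    metadata = toy$metadata
  )
  jsonlite::write_json(ff_desc, file.path(out_dir, "forcefield.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(toy)
}
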