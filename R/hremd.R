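# Hamiltonian replica-exchange controller: parallel replicas differing only
# in their bias window, neighbour exchanges by a Metropolis criterion,
# bookkeeping and walker demultiplexing.

#' Metropolis exchange exponent between two replicas
#'
#' Only the biasing term differs between replicas, so the exchange exponent
#' reduces to Delta = beta * (E_i(x_j) + E_j(x_i) - E_i(x_i) - E_j(x_j))
#' where E_k is the bias-plus-guard energy of window k. The acceptance
#' probability is min(1, exp(-Delta)); Delta is antisymmetric under swapping
#' the two roles.
#'
#' @param coords_i,coords_j current frames of the two replicas.
#' @param window_i,window_j their `BiasWindow`s.
#' @param groups a `SurfaceGroups` object.
#' @param beta inverse temperature 1/(k_B T) in (kcal/mol)^-1.
#' @param ... further arguments passed to [evaluate_bias()] (cutoff,
#'   exponent, normalization, guard settings).
#' @return dimensionless Delta.
#' @export
exchange_delta <- function(coords_i, coords_j, window_i, window_j, groups, beta, ...) {
  e_ii <- evaluate_bias(groups, coords_i, window_i, ...)$energy
  e_jj <- evaluate_bias(groups, coords_j, window_j, ...)$energy
  e_ij <- evaluate_bias(groups, coords_j, window_i, ...)$energy
  e_ji <- evaluate_bias(groups, coords_i, window_j, ...)$energy
  beta * (e_ij + e_ji - e_ii - e_jj)
}

#' Metropolis acceptance decision
#'
#' @param delta dimensionless exchange exponent.
#' @return logical: accept with probability min(1, exp(-delta)). Consumes one
#'   uniform variate from the current RNG.
#' @export
metropolis_accept <- function(delta) {
  delta <= 0 || stats::runif(1) < exp(-delta)
}

#' Attempt neighbour exchanges over one phase
#'
#' Alternates even pairs (1-2, 3-4, ...) and odd pairs (2-3, 4-5, ...)
#' between successive calls. On acceptance, coordinates and velocities swap
#' between the replica slots while the bias windows stay attached to their
#' slots; velocities are not rescaled (all replicas share one temperature).
#'
#' @param states list of `SimulationState`s, one per replica slot.
#' @param ladder a `ReplicaLadder`.
#' @param groups a `SurfaceGroups` object.
#' @param beta inverse temperature (kcal/mol)^-1.
#' @param phase 0 for even pairs, 1 for odd pairs.
#' @param exchange_stream RNG stream for the acceptance draws.
#' @param ... passed to [evaluate_bias()].
#' @return list(states, records = data.frame(i, j, delta, accepted),
#'   exchange_stream).
#' @export
attempt_exchanges <- function(states, ladder, groups, beta, phase,
                              exchange_stream, ...) {
  n <- length(states)
  first <- if (phase %% 2 == 0) 1L else 2L
  lo <- if (first <= n - 1L) seq(first, n - 1L, by = 2L) else integer()
  if (length(lo) == 0L) {
    return(list(
      states = states,
      records = data.frame(i = integer(), j = integer(), delta = numeric(), accepted = logical()),
      exchange_stream = exchange_stream
    ))
  }
  rec <- vector("list", length(lo))
  for (k in seq_along(lo)) {
    i <- lo[k]
    j <- i + 1L
    delta <- exchange_delta(
      states[[i]]$coords, states[[j]]$coords,
      ladder$windows[[i]], ladder$windows[[j]], groups, beta, ...
    )
    if (!is.finite(delta)) stop("non-finite exchange exponent")
    r <- with_stream(exchange_stream, metropolis_accept(delta))
    exchange_stream <- r$stream
    accepted <- r$value
    if (accepted) {
      tmp_x <- states[[i]]$coords
      tmp_v <- states[[i]]$velocities
      states[[i]]$coords <- states[[j]]$coords
      states[[i]]$velocities <- states[[j]]$velocities
      states[[j]]$coords <- tmp_x
      states[[j]]$velocities <- tmp_v
      # cached forces belong to the old coordinates / window: invalidate
      states[[i]]$forces <- NULL
      states[[j]]$forces <- NULL
    }
    rec[[k]] <- data.frame(i = i, j = j, delta = delta, accepted = accepted)
  }
  list(states = states, records = do.call(rbind, rec), exchange_stream = exchange_stream)
}

#' Run a Hamiltonian replica-exchange simulation
#'
#' Replica slots run sequentially in-process on independent RNG streams
#' derived from the master seed; exchanges are attempted every
#' `exchange_interval` steps, alternating even and odd neighbour phases.
#' Replica 1 is the reference replica. Deterministic for a fixed seed.
#'
#' @param system a `MolecularSystem`.
#' @param ff a `ToyForceField`.
#' @param restraints a `RestraintSet` or NULL.
#' @param groups a `SurfaceGroups` object.
#' @param ladder a `ReplicaLadder` (one window per replica).
#' @param n_steps total Langevin steps per replica.
#' @param exchange_interval steps between exchange attempts.
#' @param seed master seed (integer).
#' @param dt time step (ps).
#' @param gamma collision frequency (ps^-1).
#' @param temperature temperature (K).
#' @param record_every frame/diagnostic stride in steps.
#' @param cutoff contact cutoff (Angstrom).
#' @param exponent weighting exponent (6 or 12).
#' @param normalization see [weighted_mean_distance()].
#' @param store_frames keep coordinate frames (set FALSE to retain only
#'   diagnostics for long runs).
#' @param frozen optional frozen-coordinate mask passed to every replica.
#' @param start_coords optional list of per-replica starting frames
#'   (defaults to the system coordinates for all replicas).
#' @return A `TrajectoryStore`: list with per-replica `frames`, `diagnostics`
#'   (replica, round, step, d_ave12, n_pairs, guard_active, bias_energy,
#'   base_energy, interaction_energy), `exchanges` log, ladder and run
#'   metadata.
#' @export
run_hremd <- function(system, ff, restraints, groups, ladder,
                      n_steps, exchange_interval, seed,
                      dt = 0.01, gamma = 0.1, temperature = 300,
                      record_every = 10, cutoff = 10, exponent = 12,
                      normalization = "restricted",
                      store_frames = TRUE, frozen = NULL,
                      start_coords = NULL) {
  n_rep <- length(ladder$windows)
  beta <- 1 / (KB_KCAL * temperature)
  masses <- system$atoms$mass

  bias_closure <- function(window) {
    force(window)
    function(coords) {
      evaluate_bias(groups, coords, window,
        cutoff = cutoff, exponent = exponent,
        normalization = normalization
      )
    }
  }
  force_fns <- lapply(seq_len(n_rep), function(i) {
    bias_i <- bias_closure(ladder$windows[[i]])
    function(coords) {
      compute_energy_forces(system, ff, restraints, coords, bias = bias_i)
    }
  })

  states <- lapply(seq_len(n_rep), function(i) {
    x0 <- if (is.null(start_coords)) system$coords else start_coords[[i]]
    sim_state(x0, masses, temperature, seed = derive_seed(seed, i), frozen = frozen)
  })
  exchange_stream <- new_rng_stream(derive_seed(seed, 0L))

  n_rounds <- ceiling(n_steps / exchange_interval)
  frames <- lapply(seq_len(n_rep), function(i) list())
  diag_rows <- list()
  ex_rows <- list()
  steps_done <- 0L
  for (round in seq_len(n_rounds)) {
    seg_len <- min(exchange_interval, n_steps - steps_done)
    for (i in seq_len(n_rep)) {
      out <- run_segment(states[[i]], force_fns[[i]], seg_len,
        dt = dt, gamma = gamma, record_every = record_every
      )
      states[[i]] <- out$state
      if (!is.null(out$records)) {
        r <- out$records
        nb <- r$bias + r$guard
        d <- data.frame(
          replica = i, round = round, step = r$step,
          d_ave12 = if ("d_ave12" %in% names(r)) r$d_ave12 else NA_real_,
          n_pairs = if ("n_pairs" %in% names(r)) r$n_pairs else NA_integer_,
          guard_active = if ("guard_active" %in% names(r)) r$guard_active else NA,
          bias_energy = nb,
          base_energy = r$energy - nb
        )
        diag_rows[[length(diag_rows) + 1L]] <- d
      }
      if (store_frames && length(out$frames)) {
        frames[[i]] <- c(frames[[i]], out$frames)
      }
    }
    steps_done <- steps_done + seg_len
    if (n_rep > 1L) {
      ex <- attempt_exchanges(states, ladder, groups, beta,
        phase = (round - 1L) %% 2L,
        exchange_stream = exchange_stream,
        cutoff = cutoff, exponent = exponent, normalization = normalization
      )
      states <- ex$states
      exchange_stream <- ex$exchange_stream
      if (nrow(ex$records)) {
        ex$records$round <- round
        ex$records$step <- steps_done
        ex_rows[[length(ex_rows) + 1L]] <- ex$records
      }
    }
  }

  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else NULL
  if (!is.null(diagnostics)) {
    diagnostics <- diagnostics[order(diagnostics$replica, diagnostics$step), , drop = FALSE]
    rownames(diagnostics) <- NULL
    # receptor-ligand interaction energy per recorded frame
    if (store_frames) {
      ie <- numeric(nrow(diagnostics))
      pos <- 1L
      for (i in seq_len(n_rep)) {
        fi <- frames[[i]]
        for (k in seq_along(fi)) {
          ie[pos] <- interaction_energy(system, ff, fi[[k]])
          pos <- pos + 1L
        }
      }
      diagnostics$interaction_energy <- ie
    } else {
      diagnostics$interaction_energy <- NA_real_
    }
  }
  exchanges <- if (length(ex_rows)) {
    e <- do.call(rbind, ex_rows)
    e[, c("round", "step", "i", "j", "delta", "accepted")]
  } else {
    data.frame(
      round = integer(), step = integer(), i = integer(), j = integer(),
      delta = numeric(), accepted = logical()
    )
  }

  structure(
    list(
      n_replicas = n_rep,
      frames = frames,
      diagnostics = diagnostics,
      exchanges = exchanges,
      ladder = ladder,
      final_states = states,
      elements = system$atoms$element,
      record_every = record_every,
      exchange_interval = exchange_interval,
      n_steps = n_steps,
      seed = seed,
      temperature = temperature, dt = dt, gamma = gamma
    ),
    class = "TrajectoryStore"
  )
}

#' @export
print.TrajectoryStore <- function(x, ...) {
  cat(sprintf(
    "TrajectoryStore: %d replicas, %d steps each, %d recorded frames/replica, %d exchange attempts\n",
    x$n_replicas, x$n_steps, length(x$frames[[1L]]), nrow(x$exchanges)
  ))
  invisible(x)
}

#' Per-neighbour-pair exchange acceptance ratios
#'
#' @param records exchange log (a `TrajectoryStore` or its `exchanges`
#'   data.frame).
#' @return data.frame(i, j, attempts, accepted, ratio) plus an "overall"
#'   attribute; pairs with zero attempts report NA.
#' @export
acceptance_statistics <- function(records) {
  if (inherits(records, "TrajectoryStore")) records <- records$exchanges
  if (nrow(records) == 0L) {
    out <- data.frame(
      i = integer(), j = integer(), attempts = integer(),
      accepted = integer(), ratio = numeric()
    )
    attr(out, "overall") <- NA_real_
    return(out)
  }
  key <- paste(records$i, records$j)
  agg <- lapply(split(records, key), function(g) {
    data.frame(
      i = g$i[1L], j = g$j[1L], attempts = nrow(g),
      accepted = sum(g$accepted), ratio = mean(g$accepted)
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$i), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overall") <- mean(records$accepted)
  out
}

#' Demultiplex replica-slot trajectories into continuous walkers
#'
#' Follows each configuration through the accepted exchanges: walker w's
#' trajectory is the concatenation of the frames recorded in whichever
#' replica slot the walker occupied during each exchange round. The multiset
#' of frames at each recorded time equals the multiset across replica slots.
#'
#' @param store a `TrajectoryStore` with frames.
#' @return list with `walker_frames` (list per walker), `slot_of_walker`
#'   (rounds x walkers matrix of slot indices) and `walker_of_slot`
#'   (inverse mapping).
#' @export
demultiplex <- function(store) {
  n_rep <- store$n_replicas
  d <- store$diagnostics
  if (is.null(d)) stop("store holds no diagnostics; cannot demultiplex")
  rounds <- sort(unique(d$round))
  # walker_of_slot[r, s]: which walker occupies slot s during round r
  walker_of_slot <- matrix(NA_integer_, length(rounds), n_rep)
  cur <- seq_len(n_rep)
  ex <- store$exchanges
  for (ridx in seq_along(rounds)) {
    walker_of_slot[ridx, ] <- cur
    er <- ex[ex$round == rounds[ridx] & ex$accepted, , drop = FALSE]
    if (nrow(er)) {
      for (k in seq_len(nrow(er))) {
        tmp <- cur[er$i[k]]
        cur[er$i[k]] <- cur[er$j[k]]
        cur[er$j[k]] <- tmp
      }
    }
  }
  if (any(apply(walker_of_slot, 1L, function(r) !setequal(r, seq_len(n_rep))))) {
    stop("inconsistent exchange log: slot occupancy is not a permutation")
  }
  slot_of_walker <- matrix(0L, length(rounds), n_rep)
  for (ridx in seq_along(rounds)) {
    slot_of_walker[ridx, ] <- order(walker_of_slot[ridx, ])
  }

  walker_frames <- NULL
  if (length(store$frames[[1L]]) > 0L) {
    walker_frames <- lapply(seq_len(n_rep), function(w) list())
    # frames are stored per slot in step order; map each frame's round
    per_slot_rounds <- lapply(seq_len(n_rep), function(s) d$round[d$replica == s])
    frame_pos <- lapply(seq_len(n_rep), function(s) {
      split(seq_along(per_slot_rounds[[s]]), per_slot_rounds[[s]])
    })
    for (w in seq_len(n_rep)) {
      for (ridx in seq_along(rounds)) {
        s <- slot_of_walker[ridx, w]
        idxs <- frame_pos[[s]][[as.character(rounds[ridx])]]
        for (fi in idxs) {
          walker_frames[[w]][[length(walker_frames[[w]]) + 1L]] <- store$frames[[s]][[fi]]
        }
      }
    }
  }
  list(
    walker_frames = walker_frames,
    slot_of_walker = slot_of_walker,
    walker_of_slot = walker_of_slot,
    rounds = rounds
  )
}
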