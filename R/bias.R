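# The repulsive biasing potential: inverse-power weighted mean distance
# (d_ave-6 / d_ave-12), its analytic gradient, per-replica penalty windows
# and the dissociation guard.

#' Per-replica bias window
#'
#' The penalty-free interval of the weighted mean distance in one replica:
#' quadratic penalties k_f (d - d_low)^2 below and k_f (d - d_up)^2 above,
#' zero inside.
#'
#' @param d_low,d_up window bounds in Angstrom, 0 < d_low < d_up.
#' @param k_f force constant in kcal mol^-1 Angstrom^-2 (default 2.5; the
#'   working range is 2.5-5).
#' @return An object of class `BiasWindow`.
#' @export
bias_window <- function(d_low, d_up, k_f = 2.5) {
  if (!(d_low > 0 && d_up > d_low)) stop("require 0 < d_low < d_up")
  if (k_f < 0) stop("k_f must be >= 0")
  structure(list(d_low = d_low, d_up = d_up, k_f = k_f), class = "BiasWindow")
}

#' Ordered ladder of bias windows
#'
#' Replica 1 is the reference replica: its window permits receptor-ligand
#' contact without penalty. Lower bounds must increase strictly with the
#' replica index and consecutive windows must overlap
#' (d_low[i+1] < d_up[i]) so that neighbour exchanges stay frequent.
#'
#' @param windows list of `BiasWindow` objects, reference first.
#' @param verbatim set TRUE for the built-in presets transcribed from the
#'   published ladders; suppresses the advisory warning on non-monotone
#'   upper bounds.
#' @return An object of class `ReplicaLadder`.
#' @export
replica_ladder <- function(windows, verbatim = FALSE) {
  stopifnot(length(windows) >= 1L)
  for (w in windows) {
    if (!inherits(w, "BiasWindow")) stop("all ladder entries must be BiasWindow objects")
  }
  lows <- vapply(windows, `[[`, numeric(1), "d_low")
  ups <- vapply(windows, `[[`, numeric(1), "d_up")
  if (length(windows) > 1L) {
    if (any(diff(lows) <= 0)) stop("ladder lower bounds must increase strictly with replica index")
    if (any(lows[-1L] >= ups[-length(ups)])) {
      stop("consecutive ladder windows must overlap (d_low[i+1] < d_up[i])")
    }
    if (!verbatim && any(diff(ups) < 0)) {
      warning("ladder upper bounds are not non-decreasing")
    }
  }
  structure(list(windows = windows, verbatim = verbatim), class = "ReplicaLadder")
}

#' @export
print.ReplicaLadder <- function(x, ...) {
  cat(sprintf("ReplicaLadder with %d replicas (replica 1 = reference):\n", length(x$windows)))
  for (i in seq_along(x$windows)) {
    w <- x$windows[[i]]
    cat(sprintf("  replica %d: %.2f / %.2f A  (k_f = %.2f)\n", i, w$d_low, w$d_up, w$k_f))
  }
  invisible(x)
}

#' @export
length.ReplicaLadder <- function(x) length(x$windows)

#' Built-in replica ladders
#'
#' The three published window ladders for 6, 10 and 12 replicas, transcribed
#' verbatim (the 6-replica ladder's upper bounds are intentionally
#' non-monotone).
#'
#' @param name one of "ladder6", "ladder10", "ladder12".
#' @param k_f force constant applied to every window (default 2.5).
#' @return A `ReplicaLadder`.
#' @export
ladder_preset <- function(name = c("ladder6", "ladder10", "ladder12"), k_f = 2.5) {
  name <- match.arg(name)
  bounds <- switch(name,
    ladder6 = list(
      c(4.0, 6.0), c(5.15, 7.15), c(5.65, 7.65),
      c(6.05, 7.15), c(6.45, 7.65), c(6.75, 8.00)
    ),
    ladder10 = list(
      c(4.0, 6.0), c(4.5, 6.5), c(5.0, 7.0), c(5.5, 7.5), c(6.0, 8.0),
      c(6.5, 8.5), c(7.0, 9.0), c(7.5, 9.5), c(8.0, 10.0), c(8.5, 10.5)
    ),
    ladder12 = list(
      c(4.0, 6.0), c(4.50, 7.15), c(5.0, 7.65), c(5.3, 7.5), c(5.7, 8.0),
      c(6.0, 8.5), c(6.3, 9.0), c(6.7, 9.0), c(7.0, 9.0), c(7.3, 9.0),
      c(7.7, 9.0), c(8.0, 9.0)
    )
  )
  replica_ladder(lapply(bounds, function(b) bias_window(b[1], b[2], k_f)),
    verbatim = TRUE
  )
}

#' Inverse-power weighted mean distance between the partner surface groups
#'
#' d_ave-p = \[ (1/N) sum d_rl^(-p) \]^(-1/p) over the current contact-pair
#' list, with p = 6 or 12. The inverse-power weighting makes the shortest
#' receptor-ligand distance dominate; p = 12 sharpens that dominance. By
#' default the restricted sum is normalised by the dynamic pair count N so a
#' single contact at distance d gives d_ave = d; `normalization = "full"`
#' divides by N_r * N_l (the full group-size product) instead.
#'
#' Evaluation factors out the minimum distance so the p = 12 powers act on
#' ratios <= 1 and cannot overflow for distances >= 0.05 Angstrom.
#'
#' @param pairs a `ContactPairList` (non-empty).
#' @param exponent 6 or 12.
#' @param normalization "restricted" (default) or "full".
#' @param n_full N_r * N_l, required for `normalization = "full"`.
#' @return weighted mean distance in Angstrom.
#' @export
weighted_mean_distance <- function(pairs, exponent = 12,
                                   normalization = "restricted",
                                   n_full = NULL) {
  if (!(exponent == 6 || exponent == 12)) stop("exponent must be 6 or 12")
  if (!normalization %in% c("restricted", "full")) {
    stop("normalization must be 'restricted' or 'full'")
  }
  d <- pairs$d
  if (length(d) == 0L) {
    stop("empty contact-pair list: guard regime (use dissociation_guard)")
  }
  if (any(d < 0.05)) stop("pair distance below 0.05 A: outside the numerical range")
  norm <- switch(normalization,
    restricted = length(d),
    full = {
      if (is.null(n_full)) stop("normalization = 'full' requires n_full = N_r * N_l")
      n_full
    }
  )
  dmin <- min(d)
  s <- sum((dmin / d)^exponent) # each term <= 1
  dmin * (s / norm)^(-1 / exponent)
}

#' Piecewise-quadratic biasing energy of one replica window
#'
#' @param d_ave12 weighted mean distance (Angstrom).
#' @param window a `BiasWindow`.
#' @return energy in kcal/mol: k_f (d - d_low)^2 below the window,
#'   k_f (d - d_up)^2 above, 0 inside; continuous and C1 at both edges.
#' @export
bias_energy <- function(d_ave12, window) {
  if (d_ave12 <= window$d_low) {
    window$k_f * (d_ave12 - window$d_low)^2
  } else if (d_ave12 >= window$d_up) {
    window$k_f * (d_ave12 - window$d_up)^2
  } else {
    0
  }
}

# derivative dH/dd_ave
bias_energy_deriv <- function(d_ave12, window) {
  if (d_ave12 <= window$d_low) {
    2 * window$k_f * (d_ave12 - window$d_low)
  } else if (d_ave12 >= window$d_up) {
    2 * window$k_f * (d_ave12 - window$d_up)
  } else {
    0
  }
}

#' Analytic forces of the biasing potential
#'
#' Chain rule through the weighted mean distance:
#' dd_ave/dd_k = (d_ave / d_k)^(p+1) / N, so the largest contribution acts on
#' the shortest contact distance. Returns the full-system force matrix
#' (-gradient, kcal mol^-1 Angstrom^-1); atoms outside the pair list get zero
#' force, and net force and net torque vanish because all terms are central
#' pair forces.
#'
#' @param coords N x 3 frame.
#' @param pairs a `ContactPairList` (non-empty).
#' @param window a `BiasWindow`.
#' @param exponent 6 or 12 (default 12).
#' @inheritParams weighted_mean_distance
#' @return list(energy, forces = N x 3 matrix, d_ave).
#' @export
bias_forces <- function(coords, pairs, window, exponent = 12,
                        normalization = "restricted", n_full = NULL) {
  if (!is.matrix(coords)) coords <- as_coord_matrix(coords)
  d_ave <- weighted_mean_distance(pairs, exponent, normalization, n_full)
  energy <- bias_energy(d_ave, window)
  forces <- matrix(0, nrow(coords), 3L)
  dHdd <- bias_energy_deriv(d_ave, window)
  if (dHdd != 0) {
    norm <- if (normalization == "restricted") length(pairs$d) else n_full
    # dd_ave/dd_k, stable: ratios d_ave/d_k bounded by N^(1/p)
    w <- (d_ave / pairs$d)^(exponent + 1) / norm
    dv <- coords[pairs$ri, , drop = FALSE] - coords[pairs$li, , drop = FALSE]
    unit <- dv / pairs$d
    fpair <- -dHdd * w * unit # force on receptor atom of each pair
    forces <- forces + accumulate_pair_forces(nrow(coords), pairs$ri, pairs$li, fpair)
  }
  list(energy = energy, forces = forces, d_ave = d_ave)
}

#' Dissociation guard
#'
#' Harmonic distance restraint k (d_min - cutoff)^2 on the single closest
#' receptor-ligand surface-atom pair, active only while the contact-pair
#' list is empty (no surface pair within the cutoff); keeps the partners
#' from drifting apart in the strongly repelled replicas. Ties for the
#' closest pair break to the lowest (receptor index, ligand index).
#'
#' @param groups a `SurfaceGroups` object.
#' @param coords N x 3 frame.
#' @param cutoff pair cutoff in Angstrom (default 10).
#' @param k force constant in kcal mol^-1 Angstrom^-2 (default 2.5).
#' @return list(energy, forces = N x 3, active, pair).
#' @export
dissociation_guard <- function(groups, coords, cutoff = 10, k = 2.5) {
  coords <- as_coord_matrix(coords)
  forces <- matrix(0, nrow(coords), 3L)
  cp <- closest_surface_pair(groups, coords)
  if (cp$d < cutoff) {
    return(list(energy = 0, forces = forces, active = FALSE, pair = NULL))
  }
  dv <- coords[cp$ri, ] - coords[cp$li, ]
  dd <- cp$d - cutoff
  f <- -2 * k * dd * dv / cp$d # force on receptor atom
  forces[cp$ri, ] <- f
  forces[cp$li, ] <- -f
  list(energy = k * dd^2, forces = forces, active = TRUE, pair = cp)
}

#' Evaluate the full biasing term of one replica
#'
#' Rebuilds the contact-pair list from the current coordinates, then
#' dispatches: when pairs exist the window bias acts (guard inactive);
#' when the list is empty the dissociation guard acts instead. Exactly one
#' of the two contributions is non-zero.
#'
#' @param groups a `SurfaceGroups` object.
#' @param coords N x 3 frame.
#' @param window a `BiasWindow`.
#' @param cutoff contact cutoff (Angstrom, default 10).
#' @param exponent 6 or 12.
#' @param normalization see [weighted_mean_distance()].
#' @param guard_k guard force constant; defaults to the window's k_f.
#' @param guard_mode "empty" (default: guard when the pair list is empty) or
#'   "dave" (guard when d_ave-12 exceeds the cutoff).
#' @return list(energy, forces, d_ave12, n_pairs, guard_active).
#' @export
evaluate_bias <- function(groups, coords, window, cutoff = 10, exponent = 12,
                          normalization = "restricted",
                          guard_k = window$k_f,
                          guard_mode = "empty") {
  if (!guard_mode %in% c("empty", "dave")) stop("guard_mode must be 'empty' or 'dave'")
  if (!is.matrix(coords)) coords <- as_coord_matrix(coords)
  rsel <- groups$receptor_atoms
  lsel <- groups$ligand_atoms
  rc <- coords[rsel, , drop = FALSE]
  lc <- coords[lsel, , drop = FALSE]
  d2 <- outer(
    rc[, 1L]^2 + rc[, 2L]^2 + rc[, 3L]^2,
    lc[, 1L]^2 + lc[, 2L]^2 + lc[, 3L]^2, `+`
  ) - 2 * tcrossprod(rc, lc)
  hit <- d2 < cutoff^2
  np <- sum(hit)
  forces <- matrix(0, nrow(coords), 3L)

  if (np > 0L) {
    dh <- sqrt(d2[hit])
    if (any(dh < 0.05)) stop("pair distance below 0.05 A: outside the numerical range")
    norm <- if (normalization == "restricted") np else length(rsel) * length(lsel)
    dmin <- min(dh)
    s <- sum((dmin / dh)^exponent) # ratios <= 1: no overflow
    d_ave <- dmin * (s / norm)^(-1 / exponent)
    guard_now <- if (guard_mode == "empty") FALSE else d_ave > cutoff
    if (!guard_now) {
      dHdd <- bias_energy_deriv(d_ave, window)
      if (dHdd != 0) {
        G <- matrix(0, nrow(d2), ncol(d2))
        G[hit] <- dHdd * (d_ave / dh)^(exponent + 1) / norm / dh
        forces[rsel, ] <- -(rc * .rowSums(G, nrow(G), ncol(G)) - G %*% lc)
        forces[lsel, ] <- crossprod(G, rc) - lc * .colSums(G, nrow(G), ncol(G))
      }
      return(list(
        energy = bias_energy(d_ave, window), forces = forces,
        d_ave12 = d_ave, n_pairs = np, guard_active = FALSE
      ))
    }
    g <- dissociation_guard(groups, coords, cutoff, guard_k)
    return(list(
      energy = g$energy, forces = g$forces,
      d_ave12 = d_ave, n_pairs = np, guard_active = TRUE
    ))
  }
  g <- dissociation_guard(groups, coords, cutoff, guard_k)
  list(
    energy = g$energy, forces = g$forces,
    d_ave12 = NA_real_, n_pairs = 0L, guard_active = g$active
  )
}
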