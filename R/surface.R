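# Surface-atom selection (sphere-point accessibility) and the dynamic
# receptor-ligand contact-pair list that feeds the ambiguity distance.

#' Deterministic Fibonacci lattice on the unit sphere
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area
#'
#' Numerical sphere-point (Shrake-Rupley style) accessibility on a fixed
#' Fibonacci lattice: for each atom, test points on the sphere of radius
#' `radius + probe` are accessible when outside every neighbouring expanded
#' sphere. Deterministic for a fixed lattice size.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius (Angstrom, default 1.5).
#' @param n_sphere_points lattice size (default 960, minimum 92).
#' @return numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
atom_sasa <- function(coords, radii, probe = 1.5, n_sphere_points = 960) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("radii length must match atom count")
  if (probe <= 0) stop("probe radius must be positive")
  if (n_sphere_points < 92) stop("n_sphere_points must be >= 92")
  if (n > 1) {
    dmat <- as.matrix(stats::dist(coords))
    if (any(dmat[upper.tri(dmat)] < 1e-8)) {
      stop("coincident atom centers: SASA undefined for zero separation")
    }
  }
  lattice <- fibonacci_sphere(n_sphere_points)
  rext <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(lattice * rext[i], 2L, coords[i, ], `+`)
    accessible <- rep(TRUE, n_sphere_points)
    if (n > 1) {
      neigh <- which(dmat[i, ] < rext[i] + rext & seq_len(n) != i)
      for (j in neigh) {
        dx <- pts[, 1] - coords[j, 1]
        dy <- pts[, 2] - coords[j, 2]
        dz <- pts[, 3] - coords[j, 3]
        accessible <- accessible & (dx * dx + dy * dy + dz * dz >= rext[j]^2)
      }
    }
    areas[i] <- 4 * pi * rext[i]^2 * sum(accessible) / n_sphere_points
  }
  areas
}

#' Select the surface heavy atoms defining the ambiguity-restraint groups
#'
#' Computes per-partner accessibility on the isolated partners (receptor
#' without ligand and vice versa) in the starting conformation, excludes
#' hydrogens, and keeps atoms with accessible area at or above `min_area`.
#' The selection is made once and held fixed for the rest of a run; only the
#' contact-pair list is dynamic.
#'
#' @param system a `MolecularSystem`.
#' @param min_area selection threshold in Angstrom^2 (default 10).
#' @param probe probe radius in Angstrom (default 1.5).
#' @param n_sphere_points accessibility lattice size.
#' @return An object of class `SurfaceGroups`: list with `receptor_atoms`,
#'   `ligand_atoms` (absolute atom indices), `area` (per-atom, NA for atoms
#'   not evaluated), `min_area`, `probe`.
#' @export
select_surface_atoms <- function(system, min_area = 10, probe = 1.5,
                                 n_sphere_points = 960) {
  if (min_area < 0) stop("min_area must be >= 0")
  heavy <- is_heavy_atom(system)
  area <- rep(NA_real_, n_atoms(system))
  groups <- list()
  for (part in c("receptor", "ligand")) {
    idx <- system[[paste0(part, "_idx")]]
    idx <- idx[heavy[idx]]
    if (length(idx) == 0L) {
      stop(sprintf("no heavy atoms in the %s partner", part))
    }
    a <- atom_sasa(system$coords[idx, , drop = FALSE],
      system$atoms$radius[idx],
      probe = probe, n_sphere_points = n_sphere_points
    )
    area[idx] <- a
    sel <- idx[a >= min_area]
    if (length(sel) == 0L) {
      stop(sprintf(
        "empty surface selection for the %s partner: no heavy atom reaches %.1f A^2; reduce min_area",
        part, min_area
      ))
    }
    groups[[paste0(part, "_atoms")]] <- sel
  }
  structure(
    c(groups, list(area = area, min_area = min_area, probe = probe)),
    class = "SurfaceGroups"
  )
}

#' @export
print.SurfaceGroups <- function(x, ...) {
  cat(sprintf(
    "SurfaceGroups: %d receptor / %d ligand surface atoms (min area %.1f A^2, probe %.1f A)\n",
    length(x$receptor_atoms), length(x$ligand_atoms), x$min_area, x$probe
  ))
  invisible(x)
}

#' Build the dynamic receptor-ligand contact-pair list
#'
#' All receptor x ligand surface-atom pairs strictly closer than `cutoff`
#' (boundary equality excluded). Regenerated from the current coordinates at
#' every evaluation; an empty list is a valid result and hands control to the
#' dissociation guard.
#'
#' @param groups a `SurfaceGroups` object.
#' @param coords current N x 3 frame.
#' @param cutoff pair cutoff in Angstrom (default 10).
#' @return An object of class `ContactPairList`: list with integer vectors
#'   `ri`, `li` (absolute atom indices), `d` (distances), `cutoff`.
#' @export
build_contact_pairs <- function(groups, coords, cutoff = 10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!is.matrix(coords)) coords <- as_coord_matrix(coords)
  rsel <- groups$receptor_atoms
  lsel <- groups$ligand_atoms
  rc <- coords[rsel, , drop = FALSE]
  lc <- coords[lsel, , drop = FALSE]
  # pairwise squared-distance matrix, receptor rows x ligand cols
  d2 <- outer(rc[, 1L]^2 + rc[, 2L]^2 + rc[, 3L]^2,
              lc[, 1L]^2 + lc[, 2L]^2 + lc[, 3L]^2, `+`) -
    2 * tcrossprod(rc, lc)
  d2[d2 < 0] <- 0
  # which() on a matrix returns column-major linear indices: deterministic order
  hit <- which(d2 < cutoff^2)
  m <- length(rsel)
  r_row <- (hit - 1L) %% m + 1L
  l_col <- (hit - 1L) %/% m + 1L
  structure(
    list(
      ri = rsel[r_row], li = lsel[l_col],
      d = sqrt(d2[hit]), cutoff = cutoff
    ),
    class = "ContactPairList"
  )
}

#' Number of contact pairs
#' @param pairs a `ContactPairList`.
#' @return integer count.
#' @export
n_pairs <- function(pairs) length(pairs$d)

#' Closest receptor-ligand surface pair
#'
#' Used by the dissociation guard. Ties are broken deterministically by the
#' lexicographically lowest (receptor index, ligand index) pair.
#'
#' @param groups a `SurfaceGroups` object.
#' @param coords current frame.
#' @return list(ri, li, d).
#' @export
closest_surface_pair <- function(groups, coords) {
  if (!is.matrix(coords)) coords <- as_coord_matrix(coords)
  rsel <- groups$receptor_atoms
  lsel <- groups$ligand_atoms
  rc <- coords[rsel, , drop = FALSE]
  lc <- coords[lsel, , drop = FALSE]
  d2 <- outer(rowSums(rc^2), rowSums(lc^2), `+`) - 2 * tcrossprod(rc, lc)
  d2[d2 < 0] <- 0
  dmin <- min(d2)
  cand <- which(d2 <= dmin + 1e-12, arr.ind = TRUE)
  ord <- order(cand[, 1L], cand[, 2L])
  best <- cand[ord[1L], ]
  list(ri = rsel[best[1L]], li = lsel[best[2L]], d = sqrt(d2[best[1L], best[2L]]))
}
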