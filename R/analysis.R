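# Result metrics: ligand RMSD after receptor superposition, near-native
# fractions, leader clustering on pairwise ligand RMSD, interaction-energy
# profiles and first-passage times.

#' Kabsch least-squares superposition
#'
#' SVD-based optimal rigid superposition of the selected atoms of `mobile`
#' onto `reference`; returns a proper rotation (determinant +1) even for
#' reflective optima.
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param selection indices of the atoms defining the fit (default: all);
#'   needs >= 3 non-collinear atoms.
#' @return list(rotation 3x3, translation length-3, rmsd of the selection).
#'   The fitted mobile coordinates are `mobile %*% rotation + translation`
#'   (row-vector convention).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) stop("superposition needs at least 3 selected atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca)
  B0 <- sweep(B, 2L, cb)
  # collinearity check: rank of the centred selection
  sv_a <- svd(A0)$d
  if (sv_a[2L] < 1e-8 * max(sv_a[1L], 1)) {
    stop("degenerate (collinear) selection: superposition ill-defined")
  }
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u) # B0 ~ A0 %*% t(R) ... define row convention below
  rotation <- t(R)
  translation <- cb - as.numeric(ca %*% rotation)
  fitted <- A %*% rotation + matrix(translation, nrow(A), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = rotation, translation = translation, rmsd = rmsd)
}

apply_transform <- function(coords, transform) {
  coords %*% transform$rotation +
    matrix(transform$translation, nrow(coords), 3L, byrow = TRUE)
}

#' Ligand RMSD after receptor superposition
#'
#' Superposes the frame's receptor selection onto the reference receptor,
#' then computes the plain coordinate RMSD over the ligand selection without
#' re-fitting the ligand. Invariant under any global rigid transform of the
#' frame.
#'
#' @param frame,reference N x 3 coordinate matrices (same atom order).
#' @param receptor_sel,ligand_sel index vectors for the two selections.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(frame, reference, receptor_sel, ligand_sel) {
  tr <- kabsch_superpose(frame, reference, receptor_sel)
  fitted <- apply_transform(as_coord_matrix(frame), tr)
  dv <- fitted[ligand_sel, , drop = FALSE] - as_coord_matrix(reference)[ligand_sel, , drop = FALSE]
  sqrt(mean(rowSums(dv^2)))
}

#' Ligand RMSD series over stored frames
#'
#' @param frames list of N x 3 frames.
#' @param reference reference frame (native complex).
#' @param receptor_sel,ligand_sel selections as in [ligand_rmsd()].
#' @return numeric vector, one RMSD per frame.
#' @export
ligand_rmsd_series <- function(frames, reference, receptor_sel, ligand_sel) {
  vapply(frames, ligand_rmsd, numeric(1),
    reference = reference,
    receptor_sel = receptor_sel, ligand_sel = ligand_sel
  )
}

#' Fraction of near-native frames in a window
#'
#' Fraction of the selected frames with RMSD strictly below the threshold.
#'
#' @param series numeric RMSD series (Angstrom).
#' @param threshold RMSD threshold (Angstrom, strict "<").
#' @param frame_window optional integer range (indices) restricting the
#'   series, e.g. the second half of a run.
#' @return fraction in \[0, 1\].
#' @export
near_native_fraction <- function(series, threshold, frame_window = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!is.null(frame_window)) {
    if (length(frame_window) == 0L || min(frame_window) < 1L ||
      max(frame_window) > length(series)) {
      stop("frame_window outside the series")
    }
    series <- series[frame_window]
  }
  if (length(series) == 0L) stop("empty frame window")
  mean(series < threshold)
}

#' Leader clustering of ligand poses
#'
#' Frames are receptor-superposed onto the reference, then clustered in
#' trajectory order by the leader algorithm on pairwise ligand RMSD: a frame
#' joins the first existing cluster whose leader lies within `radius`, else
#' it founds a new cluster. Deterministic for a fixed frame order; every
#' member is certified within `radius` of its leader.
#'
#' @param frames list of N x 3 frames.
#' @param reference reference frame used for receptor superposition.
#' @param receptor_sel,ligand_sel atom selections.
#' @param radius cluster radius in Angstrom (default 4).
#' @return list(assignment, leaders, sizes) with `sizes` a data.frame sorted
#'   by descending cluster size.
#' @export
leader_cluster <- function(frames, reference, receptor_sel, ligand_sel, radius = 4) {
  if (radius <= 0) stop("radius must be positive")
  reference <- as_coord_matrix(reference)
  lig <- lapply(frames, function(fr) {
    tr <- kabsch_superpose(fr, reference, receptor_sel)
    apply_transform(as_coord_matrix(fr), tr)[ligand_sel, , drop = FALSE]
  })
  assignment <- integer(length(lig))
  leaders <- integer(0)
  for (f in seq_along(lig)) {
    placed <- FALSE
    for (c in seq_along(leaders)) {
      d <- sqrt(mean(rowSums((lig[[f]] - lig[[leaders[c]]])^2)))
      if (d < radius) {
        assignment[f] <- c
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, f)
      assignment[f] <- length(leaders)
    }
  }
  tab <- table(assignment)
  sizes <- data.frame(
    cluster = as.integer(names(tab)),
    leader_frame = leaders[as.integer(names(tab))],
    size = as.integer(tab)
  )
  sizes <- sizes[order(-sizes$size, sizes$cluster), , drop = FALSE]
  rownames(sizes) <- NULL
  list(assignment = assignment, leaders = leaders, sizes = sizes)
}

#' Receptor-ligand interaction energy along a trajectory
#'
#' Re-evaluates the cross nonbonded energy (no cutoff; no intra-partner,
#' bias, guard or restraint terms) for each stored frame of one replica and
#' pairs it with the ligand RMSD for scatter output.
#'
#' @param store a `TrajectoryStore`.
#' @param system a `MolecularSystem`.
#' @param ff a `ToyForceField`.
#' @param replica replica slot (default 1, the reference).
#' @param reference optional native frame; when given, a `rmsd` column is
#'   added (receptor superposition, heavy-atom ligand selection).
#' @param receptor_sel,ligand_sel selections for the RMSD column.
#' @return data.frame(step, energy\[, rmsd\]).
#' @export
interaction_energy_series <- function(store, system, ff, replica = 1,
                                      reference = NULL,
                                      receptor_sel = NULL, ligand_sel = NULL) {
  frames <- store$frames[[replica]]
  if (length(frames) == 0L) stop("no stored frames for this replica")
  d <- store$diagnostics
  d <- d[d$replica == replica, , drop = FALSE]
  energy <- vapply(frames, function(fr) interaction_energy(system, ff, fr), numeric(1))
  out <- data.frame(step = d$step[seq_along(frames)], energy = energy)
  if (!is.null(reference)) {
    if (is.null(receptor_sel)) receptor_sel <- system$receptor_idx
    if (is.null(ligand_sel)) ligand_sel <- system$ligand_idx
    out$rmsd <- ligand_rmsd_series(frames, reference, receptor_sel, ligand_sel)
  }
  out
}

#' First passage below an RMSD threshold
#'
#' @param series numeric RMSD series.
#' @param threshold RMSD threshold (strict "<").
#' @return 1-based index of the first frame below the threshold, or NA
#'   ("never") when no frame qualifies.
#' @export
first_passage <- function(series, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  hit <- which(series < threshold)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}
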