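# Molecular system container and structure / trajectory I/O.
#
# A MolecularSystem is a list with
#   atoms:        data.frame(serial, name, resname, chain, resid, element,
#                            radius, mass) -- one row per atom, file order
#   coords:       N x 3 matrix (Angstrom), starting conformation
#   receptor_idx: integer indices of the receptor partner
#   ligand_idx:   integer indices of the ligand partner
# The two index sets must be a disjoint cover of 1..N.

#' Construct a molecular system
#'
#' Builds the two-partner system container used throughout the package: an
#' ordered atom table, a coordinate frame and a disjoint receptor/ligand
#' partition.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resid`, `element`; optional `radius` (Angstrom) and `mass` (amu) columns
#'   are filled from built-in Bondi-radius and mass tables when absent.
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param receptor_idx,ligand_idx integer index vectors partitioning the atoms
#'   into the two binding partners.
#' @return An object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, coords, receptor_idx, ligand_idx) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (nrow(atoms) != n) stop("atoms and coords disagree on atom count")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  receptor_idx <- sort(unique(as.integer(receptor_idx)))
  ligand_idx <- sort(unique(as.integer(ligand_idx)))
  if (length(receptor_idx) == 0L || length(ligand_idx) == 0L) {
    stop("receptor and ligand index sets must both be non-empty")
  }
  if (length(intersect(receptor_idx, ligand_idx)) > 0L) {
    stop("receptor and ligand index sets overlap")
  }
  if (!setequal(union(receptor_idx, ligand_idx), seq_len(n))) {
    stop("receptor and ligand index sets must cover all atoms")
  }
  if (is.null(atoms$radius)) atoms$radius <- element_radius(atoms$element)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  structure(
    list(
      atoms = atoms, coords = coords,
      receptor_idx = receptor_idx, ligand_idx = ligand_idx
    ),
    class = "MolecularSystem"
  )
}

as_coord_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coordinates must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  coords
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat(sprintf(
    "MolecularSystem: %d atoms (%d receptor, %d ligand), chains: %s\n",
    nrow(x$coords), length(x$receptor_idx), length(x$ligand_idx),
    paste(unique(x$atoms$chain), collapse = ",")
  ))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `MolecularSystem`.
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$coords)

#' Heavy-atom (element != H) indicator
#' @param system a `MolecularSystem`.
#' @return logical vector, one entry per atom.
#' @export
is_heavy_atom <- function(system) toupper(system$atoms$element) != "H"

#' Read a PDB file into a MolecularSystem
#'
#' Parses ATOM/HETATM records (via bio3d) and assigns the receptor/ligand
#' partition by chain: by default the first chain is the receptor and all
#' remaining chains the ligand. Van der Waals radii come from a built-in
#' Bondi table (1.7 Angstrom with a warning for unknown elements).
#'
#' @param path PDB file path.
#' @param receptor_chains,ligand_chains optional character vectors of chain
#'   identifiers overriding the default split.
#' @return A `MolecularSystem`.
#' @export
read_pdb <- function(path, receptor_chains = NULL, ligand_chains = NULL) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop(sprintf("failed to parse PDB '%s': %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop(sprintf("no atoms in PDB file '%s'", path))
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- gsub("[^A-Za-z].*$", "", trimws(at$elety))
    element <- substr(element, 1L, 1L)
  }
  element[is.na(element) | element == ""] <-
    substr(trimws(at$elety[is.na(element) | element == ""]), 1L, 1L)
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resid = at$resno,
    element = element,
    stringsAsFactors = FALSE
  )
  coords <- cbind(at$x, at$y, at$z)
  chains <- unique(atoms$chain)
  if (is.null(receptor_chains) && is.null(ligand_chains)) {
    if (length(chains) < 2L) {
      stop("default chain split needs at least two chains; supply receptor_chains/ligand_chains")
    }
    receptor_chains <- chains[1L]
    ligand_chains <- setdiff(chains, receptor_chains)
  }
  if (is.null(ligand_chains)) ligand_chains <- setdiff(chains, receptor_chains)
  if (is.null(receptor_chains)) receptor_chains <- setdiff(chains, ligand_chains)
  receptor_idx <- which(atoms$chain %in% receptor_chains)
  ligand_idx <- which(atoms$chain %in% ligand_chains)
  if (length(receptor_idx) == 0L) stop("empty receptor chain selection")
  if (length(ligand_idx) == 0L) stop("empty ligand chain selection")
  molecular_system(atoms, coords, receptor_idx, ligand_idx)
}

#' Write a MolecularSystem frame to a PDB file
#'
#' @param system a `MolecularSystem`.
#' @param path output file path.
#' @param coords optional N x 3 frame overriding the system's stored
#'   coordinates.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path, coords = NULL) {
  if (is.null(coords)) coords <- system$coords
  coords <- as_coord_matrix(coords)
  if (nrow(coords) != n_atoms(system)) {
    stop("frame length does not match atom count")
  }
  if (any(abs(coords) >= 10000)) {
    stop("coordinate overflow: |x| >= 10000 A does not fit fixed PDB columns")
  }
  at <- system$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords)),
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$name,
    resid = at$resname,
    chain = at$chain,
    resno = at$resid,
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(path)
}

#' Write one replica of a trajectory store as multi-frame XYZ
#'
#' Each frame becomes one XYZ block; the comment line carries the step number
#' and the bias energy recorded for the frame.
#'
#' @param store a `TrajectoryStore` from [run_hremd()].
#' @param replica 1-based replica index.
#' @param path output file path.
#' @param elements optional character vector of element labels (defaults to
#'   the store's element labels, else "X").
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(store, replica, path, elements = NULL) {
  if (!inherits(store, "TrajectoryStore")) stop("store must be a TrajectoryStore")
  if (!(replica %in% seq_len(store$n_replicas))) {
    stop(sprintf("unknown replica %s (store has %d)", replica, store$n_replicas))
  }
  frames <- store$frames[[replica]]
  if (length(frames) == 0L) {
    warning("trajectory store holds no frames for this replica; writing empty file")
    cat("", file = path)
    return(invisible(path))
  }
  if (is.null(elements)) {
    elements <- if (!is.null(store$elements)) store$elements else rep("X", nrow(frames[[1L]]))
  }
  d <- store$diagnostics
  d <- d[d$replica == replica, , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(as.character(nrow(fr)), con)
    bias <- if (k <= nrow(d)) d$bias_energy[k] else NA_real_
    step <- if (k <= nrow(d)) d$step[k] else NA_integer_
    writeLines(sprintf("step %d bias_energy %.8f", step, bias), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", elements, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file path.
#' @return list with `frames` (list of N x 3 matrices), `comments` (character)
#'   and `elements` (from the first frame).
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  comments <- character()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("malformed XYZ frame header at line %d", i))
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(frames = frames, comments = comments, elements = elements)
}
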