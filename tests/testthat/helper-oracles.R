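# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: plain double loops, quaternion superposition,
# central finite differences and dense random sphere sampling.

# literal double-loop evaluation of the inverse-power weighted mean distance
oracle_weighted_mean <- function(rc, lc, exponent, cutoff = 10,
                                 normalization = "restricted") {
  s <- 0
  n_used <- 0L
  for (r in seq_len(nrow(rc))) {
    for (l in seq_len(nrow(lc))) {
      d <- sqrt(sum((rc[r, ] - lc[l, ])^2))
      if (d < cutoff) {
        s <- s + d^(-exponent)
        n_used <- n_used + 1L
      }
    }
  }
  if (n_used == 0L) {
    return(NA_real_)
  }
  norm <- if (normalization == "restricted") n_used else nrow(rc) * nrow(lc)
  (s / norm)^(-1 / exponent)
}

# brute-force contact pair filter, sorted by (receptor, ligand) index
oracle_contact_pairs <- function(rc, lc, cutoff = 10) {
  out <- NULL
  for (r in seq_len(nrow(rc))) {
    for (l in seq_len(nrow(lc))) {
      d <- sqrt(sum((rc[r, ] - lc[l, ])^2))
      if (d < cutoff) out <- rbind(out, c(r, l, d))
    }
  }
  out
}

# central finite-difference gradient of a scalar energy function
oracle_num_forces <- function(efun, coords, h = 1e-5, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(nrow(coords))
  f <- matrix(NA_real_, nrow(coords), 3L)
  for (i in atoms) {
    for (k in 1:3) {
      xp <- coords
      xp[i, k] <- xp[i, k] + h
      xm <- coords
      xm[i, k] <- xm[i, k] - h
      f[i, k] <- -(efun(xp) - efun(xm)) / (2 * h)
    }
  }
  f
}

# dense random sphere-point accessibility (independent of the Fibonacci path)
oracle_sasa <- function(coords, radii, probe, n_points = 1e5, seed = 99) {
  set.seed(seed)
  z <- stats::runif(n_points, -1, 1)
  phi <- stats::runif(n_points, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  pts0 <- cbind(r * cos(phi), r * sin(phi), z)
  rext <- radii + probe
  n <- nrow(coords)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(pts0 * rext[i], 2L, coords[i, ], `+`)
    ok <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      dd <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      ok <- ok & dd >= rext[j]^2
    }
    areas[i] <- 4 * pi * rext[i]^2 * mean(ok)
  }
  areas
}

# quaternion (Horn) method for optimal superposition of A onto B
oracle_quaternion_rmsd <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca)
  B0 <- sweep(B, 2L, cb)
  M <- crossprod(A0, B0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4L, 4L, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  list(rmsd = rmsd, rotation = t(R))
}

# rotation matrix about an axis (for rigid-transform invariance tests)
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle)
  s_ <- sin(angle)
  C <- 1 - c_
  matrix(c(
    c_ + u[1]^2 * C, u[1] * u[2] * C - u[3] * s_, u[1] * u[3] * C + u[2] * s_,
    u[2] * u[1] * C + u[3] * s_, c_ + u[2]^2 * C, u[2] * u[3] * C - u[1] * s_,
    u[3] * u[1] * C - u[2] * s_, u[3] * u[2] * C + u[1] * s_, c_ + u[3]^2 * C
  ), 3L, 3L, byrow = TRUE)
}

# Kolmogorov-Smirnov distance between samples and a gridded density
ks_to_density <- function(xs, grid, density) {
  cdf <- cumsum(density)
  cdf <- cdf / cdf[length(cdf)]
  Fx <- stats::approx(grid, cdf, sort(xs), rule = 2)$y
  n <- length(xs)
  max(abs(Fx - seq_len(n) / n))
}

# small two-partner random system for force/bias tests
make_random_test_system <- function(n_rec = 6, n_lig = 4, seed = 1, spread = 4) {
  set.seed(seed)
  coords <- matrix(stats::runif((n_rec + n_lig) * 3, -spread, spread), ncol = 3L)
  coords[seq_len(n_rec), 1L] <- coords[seq_len(n_rec), 1L] - spread
  coords[n_rec + seq_len(n_lig), 1L] <- coords[n_rec + seq_len(n_lig), 1L] + spread
  n <- n_rec + n_lig
  atoms <- data.frame(
    serial = seq_len(n), name = sprintf("B%d", seq_len(n)),
    resname = c(rep("REC", n_rec), rep("LIG", n_lig)),
    chain = c(rep("A", n_rec), rep("B", n_lig)),
    resid = c(seq_len(n_rec), rep(1L, n_lig)),
    element = "X", radius = 1.0, mass = 12,
    stringsAsFactors = FALSE
  )
  molecular_system(atoms, coords, seq_len(n_rec), n_rec + seq_len(n_lig))
}

all_atom_groups <- function(system) {
  structure(
    list(
      receptor_atoms = system$receptor_idx,
      ligand_atoms = system$ligand_idx,
      area = rep(NA_real_, n_atoms(system)), min_area = 0, probe = 1.5
    ),
    class = "SurfaceGroups"
  )
}
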