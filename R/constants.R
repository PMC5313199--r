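# Unit system: lengths in Angstrom, energies in kcal/mol, time in ps,
# masses in amu, temperature in K.

#' @keywords internal
#' @noRd
KB_KCAL <- 0.0019872041 # Boltzmann constant, kcal mol^-1 K^-1

# 1 kcal/mol expressed in amu Angstrom^2 ps^-2 (acceleration conversion)
AKMA <- 418.4

# Bondi van der Waals radii (Angstrom); fallback handled in element_radius()
BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92,
  X = 1.70 # generic bead used by the toy systems
)

DEFAULT_RADIUS <- 1.7

# Approximate atomic masses (amu)
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971, B = 10.81,
  X = 12.0
)

element_radius <- function(element) {
  el <- toupper(element)
  r <- unname(BONDI_RADII[el])
  if (any(is.na(r))) {
    unknown <- unique(el[is.na(r)])
    warning(sprintf(
      "unknown element(s) %s: using default vdW radius %.2f A",
      paste(unknown, collapse = ", "), DEFAULT_RADIUS
    ))
    r[is.na(r)] <- DEFAULT_RADIUS
  }
  r
}

element_mass <- function(element) {
  el <- toupper(element)
  m <- unname(ELEMENT_MASSES[el])
  m[is.na(m)] <- ELEMENT_MASSES[["X"]]
  m
}
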