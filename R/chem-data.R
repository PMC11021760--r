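# Element property tables used across the package. Values are standard
# reference data (Bondi vdW radii, Pyykko/CRC covalent radii, IUPAC masses).

.ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92
)

.COV_RADII <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84
)

.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81
)

# Allowed total valences (sum of bond orders including bonds to hydrogen) for
# the neutral element. Charges shift the allowed valence by the usual organic
# chemistry rules handled in check_valences().
.ALLOWED_VALENCE <- list(
  H = 1L, C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
  F = 1L, Cl = c(1L, 3L, 5L, 7L), Br = c(1L, 3L, 5L, 7L), I = c(1L, 3L, 5L, 7L), B = 3L
)

vdw_radius <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

covalent_radius <- function(element) {
  r <- .COV_RADII[element]
  r[is.na(r)] <- 0.77
  unname(r)
}

atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  m[is.na(m)] <- 0
  unname(m)
}
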