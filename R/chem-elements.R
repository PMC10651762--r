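# Element data for the internal molecular-graph model.
# Scope: the curation whitelist (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I)
# plus a few common extras so parsing does not fail before the whitelist
# check can produce a proper rejection reason.

.ELEMENT_NUMBERS <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Mg = 12L,
  Si = 14L, P = 15L, S = 16L, Cl = 17L, K = 19L, Ca = 20L, Fe = 26L,
  Zn = 30L, As = 33L, Se = 34L, Br = 35L, I = 53L
)

# IUPAC 2021 standard atomic weights (conventional values)
.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, I = 126.904
)

# Elements permitted by the standardization cascade
.ELEMENT_WHITELIST <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                        "Cl", "Se", "Br", "I")

# Organic-subset elements writable without brackets
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s", "se")

# Allowed total valences (bond order sum + hydrogens) per element and formal
# charge. Used both for implicit-hydrogen assignment (lowest allowed valence
# that accommodates the bonds) and for the sanitization valence check.
.allowedValences <- function(elem, charge) {
  base <- switch(elem,
    H  = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
    Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
    Se = c(2L, 4L, 6L), Br = 1L, I = c(1L, 3L, 5L, 7L),
    Na = 1L, K = 1L, Mg = 2L, Ca = 2L, Fe = c(2L, 3L), Zn = 2L,
    As = c(3L, 5L),
    integer(0))
  if (length(base) == 0L) return(base)
  if (charge == 0L) return(base)
  # Electronegative elements gain a bond when protonated/cationic and lose
  # one as anions; carbon and boron lose a bond in either ionic state.
  if (elem %in% c("N", "O", "S", "P", "Se", "As")) {
    return(pmax(base + as.integer(charge), 0L))
  }
  if (elem %in% c("F", "Cl", "Br", "I")) {
    if (charge < 0L) return(0L)
    return(pmax(base + as.integer(charge), 0L))
  }
  if (elem == "C") return(if (abs(charge) == 1L) 3L else base)
  if (elem == "B") return(if (charge == -1L) 4L else pmax(base - abs(as.integer(charge)), 0L))
  pmax(base - abs(as.integer(charge)), 0L)
}

# Valence an aromatic atom must reach once its single delocalized double
# bond (if required) is accounted for.
.aromTargetValence <- function(elem, charge) {
  v <- switch(elem,
    C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, B = 3L, Se = 2L,
    return(NA_integer_))
  if (elem %in% c("N", "O", "S", "P", "Se")) v <- v + as.integer(charge)
  if (elem == "C" && charge != 0L) v <- 3L
  v
}
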