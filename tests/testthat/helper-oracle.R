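# Independent oracles used across the suite.
#
# The mass oracle is a standalone formula parser + atomic-mass table
# (separate code path from the package internals); the digestion oracle
# enumerates all 2^(n-1) cut patterns by brute force. Literature
# monoisotopic NMP masses are frozen for cross-checks.

PROBE31 <- "GCAUCAGAAAUACACCCGUAGGGCUUUGAGA"

# Standalone elemental mass computation (monoisotopic Da).
oracle_mass <- function(formula) {
  masses <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
              O = 15.9949146221, P = 30.97376151, S = 31.97207069)
  total <- 0
  m <- gregexpr("[A-Z][a-z]*-?[0-9]*", formula)[[1]]
  for (tok in regmatches(formula, list(m))[[1]]) {
    el <- gsub("[-0-9]", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    total <- total + masses[[el]] * cnt
  }
  total
}

# Frozen literature monoisotopic masses (Da) of the four 3'-NMPs.
NMP_MASS <- c(A = 347.063084, C = 323.051851, G = 363.057999, U = 324.035867)
H2O_MASS <- 18.010565
HPO3_MASS <- 79.966331

# Neutral oligo mass from first principles: sum of NMPs minus the waters
# condensed out at each linkage, adjusted for termini.
oracle_oligo_mass <- function(bases, terminus5 = "hydroxyl",
                              terminus3 = "phosphate") {
  m <- sum(NMP_MASS[bases]) - (length(bases) - 1) * H2O_MASS
  if (terminus5 == "phosphate") m <- m + HPO3_MASS
  if (terminus3 == "cyclic_phosphate") m <- m - H2O_MASS
  if (terminus3 == "hydroxyl") m <- m - HPO3_MASS
  m
}

# Brute-force expected product counts: enumerate every cut pattern of the
# n-1 bonds, weight by its independent-cut probability, and accumulate
# the resulting segments. Bonds at probability exactly 0 or 1 are
# deterministic, so only the genuinely stochastic bonds are enumerated
# (keeps the exhaustive check feasible on sparse models of long parents).
# Returns a data.frame (start, end, expected).
oracle_expected <- function(bond_probs, n_molecules = 1) {
  nb <- length(bond_probs)
  n <- nb + 1L
  free <- which(bond_probs > 0 & bond_probs < 1)
  fixed <- which(bond_probs == 1)
  acc <- new.env(parent = emptyenv())
  for (mask in 0:(2^length(free) - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(max(length(free), 1L))]
    cuts <- integer(nb)
    cuts[fixed] <- 1L
    if (length(free)) cuts[free] <- bits[seq_along(free)]
    w <- prod(ifelse(cuts[free] == 1L, bond_probs[free],
                     1 - bond_probs[free]))
    if (w == 0) next
    bounds <- c(0L, which(cuts == 1L), n)
    for (k in seq_len(length(bounds) - 1L)) {
      key <- paste0(bounds[k] + 1L, "-", bounds[k + 1L])
      acc[[key]] <- (acc[[key]] %||% 0) + w
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, "-"))
  out <- data.frame(start = as.integer(parts[, 1]),
                    end = as.integer(parts[, 2]),
                    expected = vapply(keys, function(k) acc[[k]],
                                      numeric(1)) * n_molecules)
  out[order(out$start, out$end), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random parent sequence of plain bases under the current RNG state.
random_parent <- function(n) {
  parse_rna(paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                   collapse = ""))
}

# Random cleavage model on a probability grid under the current RNG state.
random_grid_model <- function(grid = seq(0, 1, by = 0.05)) {
  p <- matrix(sample(grid, 16, replace = TRUE), 4, 4,
              dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  cleavage_model(p)
}
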