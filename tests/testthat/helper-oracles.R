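# Shared independent oracles and small fixture builders.

# Independent formula-summation oracle over a hand-written element table
# (values typed in from the periodic table, separate from the package's).
oracle_formula_mass <- function(formula) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)
  sum(tab[names(formula)] * formula)
}

# Deterministic orientation-average of the union area of two equal disks
# (radius r, center separation d): the projected separation is d*sin(theta)
# with cos(theta) uniform on [0, 1] for a uniformly oriented axis.
oracle_diatomic_area <- function(d, r) {
  union_area <- function(dd) {
    ifelse(dd >= 2 * r, 2 * pi * r^2,
           2 * pi * r^2 - (2 * r^2 * acos(dd / (2 * r)) -
                             (dd / 2) * sqrt(pmax(4 * r^2 - dd^2, 0))))
  }
  stats::integrate(function(u) union_area(d * sqrt(1 - u^2)), 0, 1,
                   rel.tol = 1e-10)$value
}

# O(N*M) brute-force contact oracle: lipid ids in contact with the protein.
oracle_contacts <- function(prot, lip, lipid_id, cutoff) {
  ids <- sort(unique(lipid_id))
  in_contact <- vapply(ids, function(id) {
    q <- lip[lipid_id == id, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rowSums(prot^2), "+") - 2 * q %*% t(prot)
    any(d2 <= cutoff^2)
  }, logical(1))
  ids[in_contact]
}

# Minimal random membrane-like system for contact equivalence testing.
random_contact_system <- function(n_prot = 40, n_lipids = 12,
                                  atoms_per_lipid = 4, span = 30) {
  prot <- matrix(runif(n_prot * 3, -span / 3, span / 3), ncol = 3)
  lip <- matrix(runif(n_lipids * atoms_per_lipid * 3, -span, span), ncol = 3)
  list(prot = prot, lip = lip,
       lipid_id = rep(seq_len(n_lipids), each = atoms_per_lipid))
}

# Tiny trajectory with explicit topology for unit tests.
toy_trajectory <- function(frames, molecule, lipid_id, element,
                           headgroup = NULL, box = NULL) {
  n <- nrow(frames[[1]])
  sm <- structure_model(element, frames[[1]][, 1], frames[[1]][, 2],
                        frames[[1]][, 3],
                        chain = ifelse(molecule == "protein", "A", "L"),
                        resid = ifelse(is.na(lipid_id), 1L, lipid_id),
                        resname = ifelse(molecule == "protein", "PRO", "POP"))
  sm$molecule <- molecule
  sm$lipid_id <- lipid_id
  if (!is.null(headgroup)) sm$headgroup <- headgroup
  trajectory(sm, frames, box = box)
}
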