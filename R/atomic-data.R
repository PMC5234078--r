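# Embedded element tables: IUPAC standard atomic weights, principal-isotope
# monoisotopic masses, and van der Waals radii (Bondi/Rowland).  Embedded so
# mass arithmetic and CCS estimation carry no runtime data dependency.

ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973761998,
  S = 32.06, Na = 22.98976928, K = 39.0983, Cl = 35.45, Mg = 24.305,
  Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971
)

MONOISOTOPIC_MASSES <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637064864,
  Cl = 34.968852682, Mg = 23.985041697, Ca = 39.962590863,
  Fe = 55.93493633, Zn = 63.92914201, Se = 79.9165218
)

VDW_RADII <- c(
  H = 1.10, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  Na = 2.27, K = 2.75, Cl = 1.75, Mg = 1.73, Ca = 2.31, Fe = 2.00,
  Zn = 1.39, Se = 1.90
)
DEFAULT_VDW_RADIUS <- 1.70

#' Sum a molecular formula into a mass
#'
#' @param formula named integer vector, element symbol -> count.
#' @param kind `"average"` (standard atomic weights) or `"monoisotopic"`.
#' @return mass in Da.
#' @examples
#' formula_mass(c(H = 2, O = 1))  # water, 18.015
#' @export
formula_mass <- function(formula, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  tab <- if (kind == "average") ATOMIC_WEIGHTS else MONOISOTOPIC_MASSES
  el <- names(formula)
  if (is.null(el) || any(!nzchar(el))) stop("formula must be a named vector")
  unknown <- setdiff(el, names(tab))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(tab[el] * as.numeric(formula))
}

element_vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- DEFAULT_VDW_RADIUS
  unname(r)
}

# Guess the element from a PDB atom name when no element column is present.
guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  first <- substr(nm, 1, 1)
  out <- ifelse(two %in% c("NA", "CL", "MG", "FE", "ZN", "SE", "CA") &
                  nchar(atom_name) > 0 & !grepl("^[0-9 ]", atom_name) &
                  nchar(nm) == nchar(two),
                paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
                toupper(first))
  out
}
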