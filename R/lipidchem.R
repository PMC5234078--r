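# Lipid species construction and adduct-mass assignment.
#
# Species are described by a lipid class and a total acyl composition n:d
# (n = total acyl-chain carbons, d = total double bonds summed over all
# chains); the distribution of carbons among individual chains is not
# modelled.  Formulas are assembled from the class's head-group skeleton (a
# glycerol/phosphate backbone bearing the class-specific number of acyl
# chains, each chain contributing CH2 units minus H2 per double bond).
#
# Closed forms used, free acid (n = acyl carbons, d = double bonds):
#   PE  (diacyl glycerophosphoethanolamine):  C(n+5)  H(2n-2d+10) N O8  P
#   PG  (diacyl glycerophosphoglycerol):      C(n+6)  H(2n-2d+11)   O10 P
#   CDL (tetraacyl cardiolipin):              C(n+9)  H(2n-2d+14)   O17 P2
#   MAG (monoacylglycerol):                   C(n+3)  H(2n-2d+6)    O4
#
# Reported-mass convention: PE (zwitterionic), PG and MAG are reported as the
# neutral species.  Cardiolipin is a diacid whose first phosphate proton is
# essentially always dissociated; lipidomics tables for it quote the singly
# deprotonated species, and only that convention reproduces the canonical
# average masses (CDL 66:2 = 1,376.9 Da; CDL 70:3 = 1,431.0 Da) and makes a
# 1,430-Da adduct assign to 70:3 rather than 70:4.  CDL therefore defaults to
# form = "monoanion"; the neutral free acid remains available via `form`.

LIPID_CLASSES <- c("PE", "PG", "CDL", "MAG")

LIPID_CLASS_INFO <- list(
  PE  = list(n_chains = 2L, skeleton = c(C = 5, H = 10, N = 1, O = 8,  P = 1), default_form = "neutral"),
  PG  = list(n_chains = 2L, skeleton = c(C = 6, H = 11, O = 10, P = 1),        default_form = "neutral"),
  CDL = list(n_chains = 4L, skeleton = c(C = 9, H = 14, O = 17, P = 2),        default_form = "monoanion"),
  MAG = list(n_chains = 1L, skeleton = c(C = 3, H = 6,  O = 4),                default_form = "neutral")
)

#' Build a lipid species from class and total acyl composition
#'
#' Constructs the molecular formula of a lipid from its class head-group
#' skeleton plus a total acyl composition `n_carbons:n_double_bonds`, and sums
#' embedded standard atomic weights (average) and principal-isotope masses
#' (monoisotopic).
#'
#' @param lipid_class one of `"PE"`, `"PG"`, `"CDL"`, `"MAG"`.
#' @param n_carbons total acyl-chain carbons over all chains.
#' @param n_double_bonds total acyl-chain double bonds.
#' @param form reporting form: `"default"` uses the class convention (CDL
#'   singly deprotonated, others neutral); `"neutral"` or `"monoanion"`
#'   force a form.
#' @return a `lipid_species` object with fields `lipid_class`, `n_carbons`,
#'   `n_double_bonds`, `n_chains`, `form`, `molecular_formula`,
#'   `average_mass`, `monoisotopic_mass`.
#' @examples
#' build_species("CDL", 70, 3)$average_mass   # ~1430.98 Da
#' build_species("PE", 34, 1)$average_mass    # POPE, ~718.0 Da
#' @export
build_species <- function(lipid_class, n_carbons, n_double_bonds,
                          form = c("default", "neutral", "monoanion")) {
  form <- match.arg(form)
  if (!is.character(lipid_class) || length(lipid_class) != 1L ||
      !(lipid_class %in% LIPID_CLASSES)) {
    stop("unknown lipid class: ", paste(lipid_class, collapse = ","),
         " (expected one of ", paste(LIPID_CLASSES, collapse = ", "), ")")
  }
  info <- LIPID_CLASS_INFO[[lipid_class]]
  n_carbons <- as.integer(n_carbons)
  n_double_bonds <- as.integer(n_double_bonds)
  if (is.na(n_carbons) || is.na(n_double_bonds) || n_double_bonds < 0L)
    stop("negative or missing acyl composition")
  if (n_carbons < 2L * info$n_chains)
    stop("n_carbons must be at least 2 per acyl chain (", 2L * info$n_chains,
         " for ", lipid_class, ")")
  if (form == "default") form <- info$default_form

  skel <- info$skeleton
  formula <- skel
  formula["C"] <- skel[["C"]] + n_carbons
  formula["H"] <- skel[["H"]] + 2L * n_carbons - 2L * n_double_bonds
  if (form == "monoanion") formula["H"] <- formula[["H"]] - 1L
  if (formula[["H"]] < 0L) stop("composition yields a negative hydrogen count")

  structure(list(
    lipid_class = lipid_class,
    n_carbons = n_carbons,
    n_double_bonds = n_double_bonds,
    n_chains = info$n_chains,
    form = form,
    molecular_formula = formula,
    average_mass = formula_mass(formula, "average"),
    monoisotopic_mass = formula_mass(formula, "monoisotopic")
  ), class = "lipid_species")
}

#' @export
format.lipid_species <- function(x, ...) {
  sprintf("%s %d:%d (%s) %s  avg %.2f Da  mono %.2f Da",
          x$lipid_class, x$n_carbons, x$n_double_bonds, x$form,
          paste0(names(x$molecular_formula), x$molecular_formula, collapse = ""),
          x$average_mass, x$monoisotopic_mass)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Assign an observed adduct mass to a lipid composition
#'
#' Scores every composition in a search range by the absolute difference
#' between its average mass and the observed mass; ties are broken by fewer
#' double bonds, then fewer carbons.
#'
#' @param observed_mass observed neutral adduct mass (Da).
#' @param lipid_class lipid class to search.
#' @param carbons_range integer range (length 2) of total acyl carbons.
#' @param double_bonds_range integer range (length 2) of total double bonds.
#' @param carbon_step step of the carbon grid; the default 2 searches
#'   even-carbon compositions only (the biosynthetic convention), which keeps
#'   candidates at least ~2 Da apart (odd-carbon grids contain near-degenerate
#'   pairs: one extra CH2 is within 0.09 Da of seven double bonds).
#' @param form passed to [build_species()].
#' @return an `adduct_assignment` with `best_species`, `mass_error`
#'   (signed, species - observed) and `candidate_ranking` (data frame sorted
#'   ascending by absolute error).
#' @examples
#' assign_adduct(1430, "CDL")$best_species  # CDL 70:3
#' @export
assign_adduct <- function(observed_mass, lipid_class,
                          carbons_range = c(60L, 80L),
                          double_bonds_range = c(0L, 8L),
                          carbon_step = 2L, form = "default") {
  stopifnot(length(observed_mass) == 1L, is.finite(observed_mass))
  if (observed_mass <= 0) stop("observed_mass must be positive")
  cr <- as.integer(carbons_range); dr <- as.integer(double_bonds_range)
  if (length(cr) != 2L || length(dr) != 2L || cr[1] > cr[2] || dr[1] > dr[2])
    stop("invalid search range")
  n_chains <- LIPID_CLASS_INFO[[lipid_class]]$n_chains
  grid <- expand.grid(n_carbons = seq(cr[1], cr[2], by = carbon_step),
                      n_double_bonds = seq(dr[1], dr[2]))
  grid <- grid[grid$n_carbons >= 2L * n_chains, , drop = FALSE]
  if (!nrow(grid)) stop("empty candidate set for the given range")

  grid$average_mass <- vapply(seq_len(nrow(grid)), function(i) {
    build_species(lipid_class, grid$n_carbons[i], grid$n_double_bonds[i],
                  form = form)$average_mass
  }, numeric(1))
  grid$abs_error <- abs(grid$average_mass - observed_mass)
  ord <- order(grid$abs_error, grid$n_double_bonds, grid$n_carbons)
  ranking <- grid[ord, c("n_carbons", "n_double_bonds", "average_mass", "abs_error")]
  rownames(ranking) <- NULL
  best <- build_species(lipid_class, ranking$n_carbons[1],
                        ranking$n_double_bonds[1], form = form)
  structure(list(
    observed_mass = observed_mass,
    best_species = best,
    mass_error = best$average_mass - observed_mass,
    candidate_ranking = ranking
  ), class = "adduct_assignment")
}

#' @export
print.adduct_assignment <- function(x, ...) {
  cat(sprintf("observed %.2f Da -> %s %d:%d (error %+.2f Da)\n",
              x$observed_mass, x$best_species$lipid_class,
              x$best_species$n_carbons, x$best_species$n_double_bonds,
              x$mass_error))
  invisible(x)
}

#' Robust spacing of a mass series
#'
#' Median of consecutive differences of the sorted masses; used to recognise
#' acyl-chain ladders (a two-carbon saturated increment spaces average masses
#' by 28.05 Da).
#'
#' @param masses numeric vector of at least two masses (Da).
#' @return spacing in Da.
#' @export
series_spacing <- function(masses) {
  if (length(masses) < 2L) stop("need at least 2 masses")
  median(diff(sort(masses)))
}

#' Serialize lipid species / assignments to JSON
#'
#' @param x a `lipid_species` or `adduct_assignment`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
lipid_to_json <- function(x, path = NULL) {
  obj <- unclass(x)
  if (inherits(x, "adduct_assignment")) obj$best_species <- unclass(obj$best_species)
  if (inherits(x, "lipid_species") || !is.null(obj$best_species)) {
    fl <- function(s) { s$molecular_formula <- as.list(s$molecular_formula); s }
    if (inherits(x, "lipid_species")) obj <- fl(obj) else obj$best_species <- fl(obj$best_species)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
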