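# Minimal fixed-width PDB reader/writer (single- and multi-MODEL) and the
# structure_model container: one row per atom with element, coordinates (A),
# van der Waals radius, chain/residue labels.

#' Construct a structure model
#'
#' @param element element symbols.
#' @param x,y,z coordinates (A).
#' @param chain chain identifiers.
#' @param resid residue numbers.
#' @param resname residue names.
#' @param atom_name atom names.
#' @param radius van der Waals radii (A); defaults from the embedded table.
#' @param label source label.
#' @return a `structure_model` (data frame of atoms with attributes).
#' @export
structure_model <- function(element, x, y, z, chain = "A", resid = 1L,
                            resname = "UNK", atom_name = element,
                            radius = NULL, label = "") {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (!all(is.finite(c(x, y, z)))) stop("non-finite coordinates")
  element <- rep_len(element, n)
  if (is.null(radius)) radius <- element_vdw_radius(element)
  radius <- rep_len(radius, n)
  if (any(radius <= 0)) stop("radii must be positive")
  atoms <- data.frame(element = element, x = x, y = y, z = z,
                      chain = rep_len(chain, n), resid = rep_len(as.integer(resid), n),
                      resname = rep_len(resname, n),
                      atom_name = rep_len(atom_name, n), radius = radius)
  structure(atoms, class = c("structure_model", "data.frame"), label = label)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains, %d residues\n",
              nrow(x), length(unique(x$chain)),
              nrow(unique(x[c("chain", "resid")]))))
  invisible(x)
}

coords_matrix <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

parse_pdb_atom_lines <- function(lines) {
  sub6 <- function(a, b) trimws(substr(lines, a, b))
  element <- sub6(77, 78)
  nm <- sub6(13, 16)
  miss <- !nzchar(element)
  if (any(miss)) element[miss] <- guess_element(nm[miss])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  data.frame(
    atom_name = nm,
    resname = sub6(18, 20),
    chain = substr(lines, 22, 22),
    resid = as.integer(sub6(23, 26)),
    x = as.numeric(sub6(31, 38)),
    y = as.numeric(sub6(39, 46)),
    z = as.numeric(sub6(47, 54)),
    element = element)
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records; multi-MODEL files return a list of
#' `structure_model` frames plus any CRYST1 box.
#'
#' @param path PDB file path.
#' @return for a single-model file, a `structure_model`; for a multi-MODEL
#'   file, a `pdb_trajectory_raw` list with `models` and `box` (A, or NULL).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr))
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!length(model_starts)) {
    at <- parse_pdb_atom_lines(lines[is_atom])
    sm <- structure_model(at$element, at$x, at$y, at$z, at$chain, at$resid,
                          at$resname, at$atom_name, label = basename(path))
    attr(sm, "box") <- box
    return(sm)
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  models <- lapply(seq_along(model_starts), function(i) {
    idx <- seq(model_starts[i], ends[i])
    at <- parse_pdb_atom_lines(lines[idx][is_atom[idx]])
    structure_model(at$element, at$x, at$y, at$z, at$chain, at$resid,
                    at$resname, at$atom_name,
                    label = sprintf("%s#%d", basename(path), i))
  })
  structure(list(models = models, box = box), class = "pdb_trajectory_raw")
}

format_pdb_atom <- function(i, a) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          i %% 100000L, substr(a$atom_name, 1, 4), substr(a$resname, 1, 3),
          substr(a$chain, 1, 1), a$resid %% 10000L, a$x, a$y, a$z,
          toupper(a$element))
}

#' Write structure model(s) as PDB
#'
#' @param x a `structure_model` or list of them (written as MODEL blocks).
#' @param path output path.
#' @param box optional box lengths (A), written as CRYST1.
#' @export
write_pdb <- function(x, path, box = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  models <- if (inherits(x, "structure_model")) list(x) else x
  multi <- length(models) > 1L
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- models[[m]]
    writeLines(vapply(seq_len(nrow(a)), function(i) format_pdb_atom(i, a[i, ]),
                      character(1)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms of a structure model
#'
#' @param structure a `structure_model`.
#' @param chain,resname,element optional filters (vectors of allowed values).
#' @param invert return the complement instead.
#' @return the subset as a `structure_model`.
#' @export
select_atoms <- function(structure, chain = NULL, resname = NULL,
                         element = NULL, invert = FALSE) {
  keep <- rep(TRUE, nrow(structure))
  if (!is.null(chain)) keep <- keep & structure$chain %in% chain
  if (!is.null(resname)) keep <- keep & structure$resname %in% resname
  if (!is.null(element)) keep <- keep & structure$element %in% element
  if (invert) keep <- !keep
  out <- structure[keep, , drop = FALSE]
  attr(out, "label") <- attr(structure, "label")
  class(out) <- class(structure)
  out
}
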