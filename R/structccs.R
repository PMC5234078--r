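# Rotationally averaged collision cross-sections by Monte-Carlo projection
# approximation.  Each atom is a hard disk of radius (vdW radius + probe
# radius) in projection; orientations are uniform random rotations; the
# projected area is estimated by hit/miss sampling and the mean is multiplied
# by a scale factor emulating the trajectory-method calibration of
# projection-approximation values.

#' Monte-Carlo projection-approximation CCS
#'
#' @param structure a [structure_model()].
#' @param probe_radius probe (buffer-gas) radius, A; default 1.0 (the
#'   He-equivalent convention).
#' @param n_rotations number of random orientations.
#' @param n_probes hit/miss samples per orientation.
#' @param scale_factor multiplier emulating trajectory-method calibration;
#'   default 1.14.
#' @param seed optional RNG seed recorded in the output; `NULL` uses the
#'   current RNG stream.
#' @param use_hydrogens include hydrogen atoms when present.
#' @return a `ccs_estimate` with `ccs` (A^2), `standard_error` (A^2, over
#'   orientations), sampling parameters and the seed used.
#' @examples
#' s <- structure_model("C", 0, 0, 0, radius = 2)
#' pa_ccs(s, probe_radius = 1, scale_factor = 1, seed = 1)$ccs  # ~ pi * 3^2
#' @export
pa_ccs <- function(structure, probe_radius = 1.0, n_rotations = 300L,
                   n_probes = 2000L, scale_factor = 1.14, seed = NULL,
                   use_hydrogens = TRUE) {
  if (!nrow(structure)) stop("structure has no atoms")
  if (probe_radius <= 0) stop("probe radius must be positive")
  if (n_rotations < 1L || n_probes < 1L) stop("non-positive sampling counts")
  if (!use_hydrogens) structure <- select_atoms(structure, element = "H",
                                                invert = TRUE)
  if (!nrow(structure)) stop("no atoms left after hydrogen removal")
  if (!is.null(seed)) set.seed(as.integer(seed))
  areas <- pa_rotation_areas(coords_matrix(structure),
                             structure$radius + probe_radius,
                             as.integer(n_rotations), as.integer(n_probes))
  structure(list(ccs = scale_factor * mean(areas),
                 standard_error = scale_factor * sd(areas) / sqrt(length(areas)),
                 n_rotations = as.integer(n_rotations),
                 n_probes_per_rotation = as.integer(n_probes),
                 probe_radius = probe_radius, scale_factor = scale_factor,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "ccs_estimate")
}

#' @export
print.ccs_estimate <- function(x, ...) {
  cat(sprintf("ccs_estimate: %.1f +/- %.1f A^2 (%d rotations x %d probes, probe %.2f A, scale %.2f)\n",
              x$ccs, x$standard_error, x$n_rotations, x$n_probes_per_rotation,
              x$probe_radius, x$scale_factor))
  invisible(x)
}

#' Trajectory-averaged CCS over a trailing window
#'
#' Runs [pa_ccs()] on each frame in the trailing `window` fraction of the
#' trajectory (e.g. `window = 0.5` uses the last half) and reports the mean
#' and s.d. over frames.
#'
#' @param frames list of `structure_model` frames.
#' @param window trailing fraction of frames to use, in (0, 1].
#' @param ... passed to [pa_ccs()].
#' @return list with `mean_ccs`, `sd_ccs`, `per_frame` (data frame), and the
#'   frame indices used.
#' @export
trajectory_ccs <- function(frames, window = 0.5, ...) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  if (!(window > 0 && window <= 1)) stop("window must be in (0, 1]")
  n <- length(frames)
  first <- n - ceiling(window * n) + 1L
  idx <- seq(first, n)
  per <- vapply(frames[idx], function(f) pa_ccs(f, ...)$ccs, numeric(1))
  list(mean_ccs = mean(per), sd_ccs = sd(per),
       per_frame = data.frame(frame = idx, ccs = per), frames_used = idx)
}

#' CCS with and without bound ligands
#'
#' Estimates the CCS of the full complex and of the protein-only atom subset
#' of the same, unchanged conformation, using the same seed for both so the
#' orientation stream is shared.
#'
#' @param frame a `structure_model` containing protein and ligand atoms.
#' @param ligand_resnames residue names treated as ligands (e.g. lipids).
#' @param seed RNG seed shared by both estimates.
#' @param ... passed to [pa_ccs()].
#' @return list with `ccs_full` and `ccs_protein_only` (`ccs_estimate`s).
#' @export
ccs_with_without_ligands <- function(frame, ligand_resnames, seed = 1L, ...) {
  protein <- select_atoms(frame, resname = ligand_resnames, invert = TRUE)
  if (!nrow(protein)) stop("empty protein selection")
  list(ccs_full = pa_ccs(frame, seed = seed, ...),
       ccs_protein_only = pa_ccs(protein, seed = seed, ...))
}
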