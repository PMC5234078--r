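# Protein-lipid geometry in trajectories: alignment, contact detection,
# clash removal, leaflet assignment, annular-shell selection, and the
# trajectory container itself.  Coordinates are Angstrom throughout;
# densities are converted to nm^-3 only at output.

#' Construct a trajectory
#'
#' @param topology a `structure_model` augmented with columns `molecule`
#'   (`"protein"` or `"lipid"`), `lipid_id` (integer per lipid molecule, `NA`
#'   for protein atoms) and optionally `headgroup` (logical, lipid head-group
#'   atoms; defaults to the phosphorus atom plus atoms of the same residue
#'   not named `C*`).
#' @param frames list of n_atoms x 3 coordinate matrices (A).
#' @param box orthorhombic box lengths, length-3 vector or n_frames x 3
#'   matrix (A); may be `NULL` for non-periodic systems.
#' @param time frame times (ns), strictly increasing.
#' @return a `md_trajectory`.
#' @export
trajectory <- function(topology, frames, box = NULL, time = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- nrow(topology)
  if (!all(vapply(frames, function(f) is.matrix(f) && nrow(f) == n &&
                    ncol(f) == 3L, logical(1))))
    stop("every frame must be an n_atoms x 3 matrix matching the topology")
  if (is.null(time)) time <- 0.1 * (seq_along(frames) - 1)
  if (any(diff(time) <= 0)) stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = length(frames), ncol = 3,
                                         byrow = TRUE)
    stopifnot(nrow(box) == length(frames), ncol(box) == 3L)
  }
  if (!"molecule" %in% names(topology)) stop("topology needs a 'molecule' column")
  if (!"lipid_id" %in% names(topology)) stop("topology needs a 'lipid_id' column")
  lip <- topology$molecule == "lipid"
  # phospholipids carry exactly one head-group phosphorus
  if (any(lip)) {
    p_per <- tapply(topology$element[lip] == "P", topology$lipid_id[lip], sum)
    if (any(p_per > 1L))
      stop("a lipid has more than one phosphorus atom")
  }
  if (!"headgroup" %in% names(topology)) {
    topology$headgroup <- lip & (topology$element == "P" |
                                   !grepl("^C", topology$atom_name))
  }
  structure(list(topology = topology, frames = frames, box = box,
                 time = as.numeric(time)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d atoms (%d protein, %d lipids)\n",
              length(x$frames), nrow(x$topology),
              sum(x$topology$molecule == "protein"),
              length(unique(stats::na.omit(x$topology$lipid_id)))))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

lipid_ids <- function(traj) {
  sort(unique(traj$topology$lipid_id[traj$topology$molecule == "lipid"]))
}

protein_index <- function(traj) which(traj$topology$molecule == "protein")

# Least-squares (Kabsch) superposition of moving onto fixed; returns the
# 3x3 rotation and translation such that moving %*% R + t approximates fixed.
kabsch <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  H <- t(sweep(moving, 2, cm)) %*% sweep(fixed, 2, cf)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cf - as.vector(cm %*% R))
}

#' Rigidly align all frames onto frame 1
#'
#' Each frame is superposed onto the first by the least-squares rotation and
#' translation of the reference selection (default: all protein atoms).
#'
#' @param traj an `md_trajectory`.
#' @param reference_selection integer or logical index into the atoms used as
#'   the alignment reference.
#' @return the aligned trajectory; attribute `rmsd` holds per-frame reference
#'   RMSD after alignment.
#' @export
align_frames <- function(traj, reference_selection = NULL) {
  if (is.null(reference_selection)) reference_selection <- protein_index(traj)
  ref <- reference_selection
  if (is.logical(ref)) ref <- which(ref)
  if (!length(ref)) stop("empty reference selection")
  if (length(ref) < 3L) stop("need >= 3 reference atoms for a rotation")
  target <- traj$frames[[1]][ref, , drop = FALSE]
  rmsd <- numeric(n_frames(traj))
  for (i in seq_along(traj$frames)) {
    fit <- kabsch(target, traj$frames[[i]][ref, , drop = FALSE])
    traj$frames[[i]] <- sweep(traj$frames[[i]] %*% fit$R, 2, fit$t, "+")
    d <- traj$frames[[i]][ref, , drop = FALSE] - target
    rmsd[i] <- sqrt(mean(rowSums(d^2)))
  }
  attr(traj, "rmsd") <- rmsd
  traj
}

#' Detect lipid-protein contacts
#'
#' A lipid is in contact in a frame iff the minimum distance between its
#' selected atoms and any protein atom is at most `cutoff` (inclusive).  The
#' cell-list accelerated kernel is exact (equal to a brute-force scan).
#'
#' @param traj an `md_trajectory`.
#' @param cutoff contact cutoff (A); default 2.15.
#' @param lipid_part `"headgroup"` (default) tests head-group atoms only,
#'   `"whole"` tests all lipid atoms.
#' @return a `contact_table`: logical matrix `in_contact` (frames x lipids),
#'   per-lipid `occupancy`, `lipid_ids`, and the parameters used.
#' @export
detect_contacts <- function(traj, cutoff = 2.15,
                            lipid_part = c("headgroup", "whole")) {
  lipid_part <- match.arg(lipid_part)
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  ids <- lipid_ids(traj)
  prot <- protein_index(traj)
  sel <- top$molecule == "lipid"
  if (lipid_part == "headgroup") sel <- sel & top$headgroup
  qidx <- which(sel)
  nf <- n_frames(traj)
  mat <- matrix(FALSE, nf, length(ids), dimnames = list(NULL, ids))
  if (length(ids) && length(qidx)) {
    grp <- match(top$lipid_id[qidx], ids) - 1L
    for (f in seq_len(nf)) {
      dmin <- min_dist_per_group(traj$frames[[f]][prot, , drop = FALSE],
                                 traj$frames[[f]][qidx, , drop = FALSE],
                                 grp, length(ids), cutoff)
      mat[f, ] <- dmin <= cutoff
    }
  }
  structure(list(in_contact = mat, occupancy = colMeans(mat),
                 lipid_ids = ids, cutoff = cutoff, lipid_part = lipid_part,
                 n_frames = nf),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table: %d frames x %d lipids (cutoff %.2f A, %s atoms); %d lipids ever in contact\n",
              x$n_frames, length(x$lipid_ids), x$cutoff, x$lipid_part,
              sum(x$occupancy > 0)))
  invisible(x)
}

#' Remove lipids clashing with the protein
#'
#' A whole lipid is removed if any of its atoms lies within `cutoff` of any
#' protein atom in the given frame (heavy clash).
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index used for the clash test.
#' @param cutoff clash cutoff (A); default 0.5.
#' @return list with `trajectory` (clashing lipids removed from topology and
#'   every frame), `removed_ids`, `n_removed`.
#' @export
remove_clashing_lipids <- function(traj, frame = 1L, cutoff = 0.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  ids <- lipid_ids(traj)
  if (!length(ids))
    return(list(trajectory = traj, removed_ids = integer(0), n_removed = 0L))
  qidx <- which(top$molecule == "lipid")
  grp <- match(top$lipid_id[qidx], ids) - 1L
  dmin <- min_dist_per_group(traj$frames[[frame]][protein_index(traj), , drop = FALSE],
                             traj$frames[[frame]][qidx, , drop = FALSE],
                             grp, length(ids), cutoff)
  removed <- ids[dmin <= cutoff]
  keep <- !(top$lipid_id %in% removed) | top$molecule != "lipid"
  traj$topology <- top[keep, , drop = FALSE]
  traj$frames <- lapply(traj$frames, function(f) f[keep, , drop = FALSE])
  list(trajectory = traj, removed_ids = removed, n_removed = length(removed))
}

#' Assign lipids to leaflets
#'
#' Lipids are assigned by the position of their head-group phosphorus along
#' the membrane normal (z) relative to the midplane, taken as the median
#' phosphorus z of the frame.  A lipid exactly at the midplane is assigned to
#' the leaflet whose mean phosphorus position is nearer.
#'
#' @param traj an `md_trajectory`.
#' @param frame frame index used for the assignment.
#' @return named character vector (`"lower"`/`"upper"`) indexed by lipid id.
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  top <- traj$topology
  pidx <- which(top$molecule == "lipid" & top$element == "P")
  if (length(pidx) < 2L) stop("need at least 2 phospholipids")
  z <- traj$frames[[frame]][pidx, 3]
  ids <- top$lipid_id[pidx]
  # midplane: initialized at the median phosphorus z, refined to the midpoint
  # of the two leaflet centroids (robust to unequal leaflet populations)
  mid <- median(z)
  for (it in 1:10) {
    up <- z > mid; lo <- z < mid
    if (!any(up) || !any(lo)) break
    new_mid <- (mean(z[up]) + mean(z[lo])) / 2
    if (abs(new_mid - mid) < 1e-9) break
    mid <- new_mid
  }
  leaf <- ifelse(z > mid, "upper", ifelse(z < mid, "lower", NA))
  if (anyNA(leaf)) {
    mu_up <- mean(z[z > mid]); mu_lo <- mean(z[z < mid])
    tie <- which(is.na(leaf))
    leaf[tie] <- ifelse(abs(z[tie] - mu_up) <= abs(z[tie] - mu_lo),
                        "upper", "lower")
  }
  setNames(leaf, ids)
}

#' Select the first annular lipid shell
#'
#' Lipids whose contact occupancy reaches `occupancy_min` ("full contact"),
#' reported with per-leaflet counts and ordered by descending occupancy then
#' lipid id.
#'
#' @param contacts a `contact_table`.
#' @param occupancy_min minimum occupancy, default 0.9.
#' @param leaflets leaflet assignment from [assign_leaflets()].
#' @return list with `lipid_ids`, `occupancy`, `per_leaflet` counts, and the
#'   `table` data frame.
#' @export
select_annular_shell <- function(contacts, occupancy_min = 0.9,
                                 leaflets = NULL) {
  occ <- contacts$occupancy
  sel <- occ >= occupancy_min
  ids <- contacts$lipid_ids[sel]
  occ <- occ[sel]
  ord <- order(-occ, ids)
  ids <- ids[ord]; occ <- occ[ord]
  leaf <- if (is.null(leaflets)) rep(NA_character_, length(ids))
    else unname(leaflets[as.character(ids)])
  per_leaflet <- if (all(is.na(leaf))) NULL else table(leaf)
  list(lipid_ids = ids, occupancy = unname(occ), per_leaflet = per_leaflet,
       table = data.frame(lipid_id = ids, occupancy = unname(occ),
                          leaflet = leaf))
}
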