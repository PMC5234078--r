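# Lipid-protein hydrogen-bond statistics with the common geometric criterion:
# donor-acceptor distance <= d_max and donor-hydrogen-acceptor angle >=
# angle_min.  Donors are N/O heavy atoms with a covalently attached hydrogen
# (H within `dh_max` of the heavy atom, same molecule); acceptors are N/O.

find_donor_hydrogens <- function(top, coords, dh_max = 1.25) {
  polar <- which(top$element %in% c("N", "O"))
  hyd <- which(top$element == "H")
  if (!length(polar) || !length(hyd)) return(NULL)
  out <- NULL
  for (h in hyd) {
    d2 <- (coords[polar, 1] - coords[h, 1])^2 +
      (coords[polar, 2] - coords[h, 2])^2 +
      (coords[polar, 3] - coords[h, 3])^2
    same_mol <- top$molecule[polar] == top$molecule[h]
    if (top$molecule[h] == "lipid")
      same_mol <- same_mol & !is.na(top$lipid_id[polar]) &
        top$lipid_id[polar] == top$lipid_id[h]
    cand <- which(d2 <= dh_max^2 & same_mol)
    if (length(cand)) {
      don <- polar[cand[which.min(d2[cand])]]
      out <- rbind(out, c(donor = don, hydrogen = h))
    }
  }
  out
}

hbond_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Count lipid-protein hydrogen bonds
#'
#' Counts, per frame and per shell lipid, hydrogen bonds between the lipid
#' head group and the protein (both donor directions), and summarizes the
#' mean number of bonds per bound lipid per frame.
#'
#' @param traj an `md_trajectory` with hydrogens present.
#' @param shell lipid ids to analyze (e.g. from [select_annular_shell()]).
#' @param d_max donor-acceptor distance cutoff (A), default 3.5.
#' @param angle_min donor-hydrogen-acceptor angle minimum (deg), default 150.
#' @return an `hbond_stats`: `bonds` (data frame: frame, lipid_id, donor,
#'   hydrogen, acceptor, distance, angle), `per_lipid_mean`, and
#'   `mean_per_lipid` (grand mean bonds per shell lipid per frame).
#' @export
count_hbonds <- function(traj, shell, d_max = 3.5, angle_min = 150) {
  top <- traj$topology
  if (!any(top$element == "H")) stop("no hydrogen atoms in the topology")
  if (!length(shell)) stop("empty lipid shell")
  prot <- protein_index(traj)
  polar_prot <- prot[top$element[prot] %in% c("N", "O")]
  if (!length(polar_prot)) stop("no polar protein atoms")
  dh <- find_donor_hydrogens(top, traj$frames[[1]])
  rows <- list()
  for (f in seq_len(n_frames(traj))) {
    co <- traj$frames[[f]]
    for (lid in shell) {
      latoms <- which(top$molecule == "lipid" & top$lipid_id == lid)
      lip_polar <- latoms[top$element[latoms] %in% c("N", "O")]
      # lipid donor -> protein acceptor
      ldh <- dh[dh[, "donor"] %in% latoms, , drop = FALSE]
      pdh <- dh[dh[, "donor"] %in% polar_prot, , drop = FALSE]
      pairs <- rbind(
        if (!is.null(ldh) && nrow(ldh))
          expand_pairs(ldh, polar_prot) else NULL,
        if (!is.null(pdh) && nrow(pdh) && length(lip_polar))
          expand_pairs(pdh, lip_polar) else NULL)
      if (is.null(pairs) || !nrow(pairs)) next
      dvec <- sqrt(rowSums((co[pairs$donor, , drop = FALSE] -
                              co[pairs$acceptor, , drop = FALSE])^2))
      ok <- dvec <= d_max
      if (!any(ok)) next
      pairs <- pairs[ok, , drop = FALSE]; dvec <- dvec[ok]
      ang <- vapply(seq_len(nrow(pairs)), function(r)
        hbond_angle(co[pairs$donor[r], ], co[pairs$hydrogen[r], ],
                    co[pairs$acceptor[r], ]), numeric(1))
      ok2 <- ang >= angle_min
      if (!any(ok2)) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, lipid_id = lid, donor = pairs$donor[ok2],
        hydrogen = pairs$hydrogen[ok2], acceptor = pairs$acceptor[ok2],
        distance = dvec[ok2], angle = ang[ok2])
    }
  }
  bonds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), lipid_id = integer(0), donor = integer(0),
               hydrogen = integer(0), acceptor = integer(0),
               distance = numeric(0), angle = numeric(0))
  nf <- n_frames(traj)
  per_lipid <- vapply(shell, function(lid)
    sum(bonds$lipid_id == lid) / nf, numeric(1))
  structure(list(bonds = bonds,
                 per_lipid_mean = setNames(per_lipid, shell),
                 mean_per_lipid = mean(per_lipid),
                 d_max = d_max, angle_min = angle_min),
            class = "hbond_stats")
}

expand_pairs <- function(dh, acceptors) {
  g <- expand.grid(i = seq_len(nrow(dh)), acceptor = acceptors)
  data.frame(donor = dh[g$i, "donor"], hydrogen = dh[g$i, "hydrogen"],
             acceptor = g$acceptor)
}

#' @export
print.hbond_stats <- function(x, ...) {
  cat(sprintf("hbond_stats: %d bonds, mean %.2f per lipid per frame (d <= %.2f A, angle >= %.0f deg)\n",
              nrow(x$bonds), x$mean_per_lipid, x$d_max, x$angle_min))
  invisible(x)
}
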