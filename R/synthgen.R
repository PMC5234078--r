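# Synthetic-data generators with planted ground truth.  Every generator is
# deterministic under a fixed seed; the returned `ground_truth` carries the
# generator name, seed and all planted parameters, and is sufficient to
# regenerate the dataset bit-identically.

ground_truth <- function(generator, seed, parameters) {
  structure(list(generator = generator,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 parameters = parameters),
            class = "ground_truth")
}

#' Write a ground-truth sidecar as JSON
#'
#' @param gt a `ground_truth`.
#' @param path output path.
#' @export
write_ground_truth <- function(gt, path) {
  writeLines(jsonlite::toJSON(unclass(gt), auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Generate a synthetic native mass spectrum
#'
#' Gaussian peaks at the theoretical m/z of every
#' (species, charge, n_adducts) combination.  Charge envelopes are Gaussian
#' over each species' charge range; adduct intensities follow the Poisson
#' pmf with mean `lambda`; baseline noise is uniform with amplitude
#' `max peak / snr`.
#'
#' @param species list of [species_model()] objects.
#' @param abundances relative species abundances (recycled to length).
#' @param lambda Poisson mean adduct occupancy.
#' @param snr signal-to-noise ratio (> 0).
#' @param mz_sigma Gaussian peak width (Th).
#' @param mz_step m/z grid step (Th).
#' @param collision_voltage,lipid_concentration metadata planted on the
#'   spectrum.
#' @param seed RNG seed.
#' @return list with `spectrum` (a [mass_spectrum()]) and `truth`.
#' @export
gen_spectrum <- function(species, abundances = 1, lambda = 0, snr = 100,
                         mz_sigma = 2, mz_step = 0.5,
                         collision_voltage = 50, lipid_concentration = NA,
                         seed = 1L) {
  if (!length(species)) stop("empty species list")
  if (inherits(species, "species_model")) species <- list(species)
  stopifnot(lambda >= 0, snr > 0)
  .seed_guard(seed)
  abundances <- rep_len(abundances, length(species))
  theo <- do.call(rbind, lapply(seq_along(species), function(si) {
    sp <- species[[si]]
    charges <- seq(sp$charge_range[1], sp$charge_range[2])
    zc <- mean(charges)
    zw <- max((sp$charge_range[2] - sp$charge_range[1]) / 3, 0.5)
    grid <- expand.grid(charge = charges, n_adducts = 0:sp$max_adducts)
    wz <- dnorm(grid$charge, zc, zw)
    wa <- if (sp$max_adducts > 0) dpois(grid$n_adducts, lambda) else 1
    data.frame(mz = theoretical_mz(sp, grid$charge, grid$n_adducts),
               w = abundances[si] * wz * wa)
  }))
  mz <- seq(min(theo$mz) - 30, max(theo$mz) + 30, by = mz_step)
  intensity <- rep(0, length(mz))
  for (i in seq_len(nrow(theo)))
    intensity <- intensity + theo$w[i] * dnorm(mz, theo$mz[i], mz_sigma)
  peak_max <- max(intensity)
  intensity <- intensity + runif(length(mz), 0, peak_max / snr)
  sp <- mass_spectrum(mz, intensity, collision_voltage = collision_voltage,
                      lipid_concentration = lipid_concentration,
                      label = "synthetic")
  truth <- ground_truth("gen_spectrum", seed, list(
    base_masses = vapply(species, `[[`, numeric(1), "base_mass"),
    oligomer_states = vapply(species, `[[`, integer(1), "oligomer_state"),
    abundances = abundances, lambda = lambda, snr = snr,
    mz_sigma = mz_sigma))
  list(spectrum = sp, truth = truth)
}

#' Default synthetic traveling-wave calibration
#'
#' A calibration fitted to noise-free points generated from the power law
#' `W' = A * t'^B`, spanning the CCS range of large protein complexes; used
#' by [gen_ciu()] to render CCS-space populations into arrival times.
#'
#' @param A,B true power-law coefficients.
#' @param edc dead-time coefficient.
#' @return a fitted `ccs_calibration` (exact by construction).
#' @export
default_calibration <- function(A = 400, B = 0.55, edc = 1.41) {
  cal <- data.frame(
    name = c("cal30k", "cal60k", "cal100k", "cal150k", "cal200k"),
    charge = c(10L, 12L, 15L, 18L, 21L),
    reference_ccs = c(2500, 4000, 5500, 7200, 9000),
    mass = c(30000, 60000, 100000, 150000, 200000))
  mz <- (cal$mass + cal$charge * PROTON_MASS) / cal$charge
  mu <- cal$mass * N2_MASS / (cal$mass + N2_MASS)
  wp <- cal$reference_ccs * sqrt(mu) / cal$charge
  cal$arrival_time <- (wp / A)^(1 / B) + edc * sqrt(mz) / 1000
  fit_calibration(cal, edc = edc)
}

#' Generate a synthetic CIU surface as an arrival-time-distribution stack
#'
#' Two-state mode: per energy column, a mixture of Gaussian compact and
#' unfolded CCS populations with compact weight following a descending
#' logistic whose value is 0.9 at `onset` and 0.5 at `midpoint`.  Gradual
#' mode: a single Gaussian whose mean ramps between the two CCS values along
#' the same logistic.  Columns are rendered into arrival times through the
#' inverse calibration (with the Jacobian of the CCS-time map).
#'
#' @param compact_ccs,unfolded_ccs planted CCS values (A^2),
#'   `unfolded_ccs > compact_ccs`.
#' @param onset,midpoint planted energies (eV), `onset <= midpoint`.
#' @param mode `"two_state"` or `"gradual"`.
#' @param charge charge state; collision voltages are `energies / charge`.
#' @param mass ion mass (Da).
#' @param energies lab-frame energy axis (eV).
#' @param ccs_sigma population width (A^2).
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param n_time arrival-time grid size.
#' @param cal calibration used for rendering; default [default_calibration()].
#' @param seed RNG seed.
#' @return list with `atd` (stack as in [read_atd_stack()]), `cal`, `truth`.
#' @export
gen_ciu <- function(compact_ccs = 5000, unfolded_ccs = 6000, onset = 900,
                    midpoint = 1100, mode = c("two_state", "gradual"),
                    charge = 11L, mass = 82450,
                    energies = seq(400, 2400, by = 100),
                    ccs_sigma = 100, snr = Inf, n_time = 150,
                    cal = default_calibration(), seed = 1L) {
  mode <- match.arg(mode)
  if (unfolded_ccs <= compact_ccs) stop("unfolded_ccs must exceed compact_ccs")
  if (onset > midpoint) stop("onset must not exceed midpoint")
  if (any(energies <= 0) || any(diff(energies) <= 0))
    stop("inconsistent energies")
  .seed_guard(seed)
  width <- max((midpoint - onset) / log(9), 1e-6)
  w_compact <- 1 / (1 + exp((energies - midpoint) / width))
  ccs_lo <- compact_ccs - 5 * ccs_sigma
  ccs_hi <- unfolded_ccs + 5 * ccs_sigma
  t_axis <- seq(invert_calibration(cal, ccs_lo, charge, mass),
                invert_calibration(cal, ccs_hi, charge, mass),
                length.out = n_time)
  ccs_of_t <- apply_calibration(cal, t_axis, charge, mass)
  jac <- c(diff(ccs_of_t)[1], diff(ccs_of_t))  # dCCS/dt per bin
  M <- matrix(0, n_time, length(energies))
  for (j in seq_along(energies)) {
    dens <- if (mode == "two_state") {
      w_compact[j] * dnorm(ccs_of_t, compact_ccs, ccs_sigma) +
        (1 - w_compact[j]) * dnorm(ccs_of_t, unfolded_ccs, ccs_sigma)
    } else {
      mu <- w_compact[j] * compact_ccs + (1 - w_compact[j]) * unfolded_ccs
      dnorm(ccs_of_t, mu, ccs_sigma)
    }
    M[, j] <- dens * jac
  }
  if (is.finite(snr)) {
    # counting-statistics noise (sd ~ sqrt(signal), peak sd = peak/snr) plus
    # a weak uniform baseline an order of magnitude below it
    peak <- max(M)
    M <- M + rnorm(length(M), 0, sqrt(pmax(M, 0) * peak) / snr) +
      runif(length(M), 0, peak / (10 * snr))
    M <- pmax(M, 0)
  }
  atd <- list(arrival_time = t_axis, voltage = energies / charge,
              intensity = M, charge = as.integer(charge))
  truth <- ground_truth("gen_ciu", seed, list(
    compact_ccs = compact_ccs, unfolded_ccs = unfolded_ccs,
    percent_expansion = 100 * (unfolded_ccs - compact_ccs) / compact_ccs,
    onset = onset, midpoint = midpoint, mode = mode, charge = charge,
    mass = mass, ccs_sigma = ccs_sigma, snr = snr))
  list(atd = atd, cal = cal, truth = truth)
}

# -- membrane generator -------------------------------------------------

toy_protein <- function(radius = 15, half_height = 25, center = c(0, 0, 0),
                        n_rings = 12L, per_ring = 24L) {
  zs <- seq(-half_height, half_height, length.out = n_rings)
  ang <- seq(0, 2 * pi, length.out = per_ring + 1L)[-1]
  g <- expand.grid(z = zs, a = ang)
  data.frame(x = center[1] + radius * cos(g$a),
             y = center[2] + radius * sin(g$a),
             z = center[3] + g$z)
}

#' Generate a synthetic membrane trajectory with planted ground truth
#'
#' Builds a planar bilayer (normal z, leaflet phosphates at `+/- leaflet_z`)
#' around a rigid cylindrical point-model protein, and plants: an annular
#' shell of persistent contact lipids with a stated leaflet split, transient
#' contact lipids, a radial thickness depression, heavy-clash lipids, and
#' ideal hydrogen-bond geometries on the shell lipids.  Frames carry
#' independent thermal jitter on non-planted atoms.
#'
#' @param n_lipids bulk (non-contacting) lipids; default 380, the occupancy
#'   of a 120 x 95 A PE bilayer at ~60 A^2 per lipid.
#' @param box orthorhombic box lengths (A).
#' @param leaflet_z leaflet phosphate half-separation (A); bulk thickness is
#'   `2 * leaflet_z`.
#' @param shell_split planted persistent shell, lipids per (lower, upper)
#'   leaflet; default `c(10, 13)`.
#' @param n_transient lipids contacting in a fraction of frames.
#' @param transient_occupancy planted occupancy of transient lipids.
#' @param n_clashes lipids planted to clash (atom at 0.3 A from protein).
#' @param hbonds_per_lipid ideal planted H-bond geometries per shell lipid
#'   (D-A 2.8 A, angle 180 deg).
#' @param depression list with `center` (xy), `depth` (A, total thickness
#'   reduction) and `sigma` (A) planting a radial thinning; `NULL` for none.
#' @param contact_distance planted distance of shell head-group contact
#'   atoms from the protein surface (A), within the 2.15 A criterion.
#' @param n_frames number of frames.
#' @param jitter thermal jitter s.d. (A) on non-planted atoms.
#' @param seed RNG seed.
#' @return list with `trajectory` (an [trajectory()]) and `truth`.
#' @export
gen_membrane <- function(n_lipids = 380L, box = c(120, 95, 100),
                         leaflet_z = 19, shell_split = c(10L, 13L),
                         n_transient = 6L, transient_occupancy = 0.5,
                         n_clashes = 0L, hbonds_per_lipid = 3L,
                         depression = NULL, contact_distance = 2.0,
                         n_frames = 10L, jitter = 0.2, seed = 1L) {
  stopifnot(n_lipids >= 0L, n_frames >= 1L, leaflet_z > 0)
  .seed_guard(seed)
  center <- c(box[1] / 2, box[2] / 2, 0)
  prot_xyz <- toy_protein(center = center)
  prot_radius <- 15
  n_shell <- sum(shell_split)

  atoms <- list(); coords0 <- list(); lid <- 0L
  add_atoms <- function(el, xyz, mol, lipid_id, head, name = el, planted = FALSE) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      element = el, atom_name = name, molecule = mol,
      lipid_id = lipid_id, headgroup = head, planted = planted)
    coords0[[length(coords0) + 1L]] <<- xyz
  }
  add_atoms(rep("C", nrow(prot_xyz)), as.matrix(prot_xyz), "protein",
            NA_integer_, FALSE, planted = TRUE)

  leaf_z_at <- function(x, y, side) {
    z <- side * leaflet_z
    if (!is.null(depression)) {
      r2 <- (x - depression$center[1])^2 + (y - depression$center[2])^2
      z <- z - side * (depression$depth / 2) * exp(-r2 / (2 * depression$sigma^2))
    }
    z
  }

  # one lipid: P at the leaflet surface, head-group O atoms, two C tails
  make_bulk_lipid <- function(x, y, side) {
    lid <<- lid + 1L
    zP <- leaf_z_at(x, y, side)
    xyz <- rbind(c(x, y, zP),
                 c(x + 0.8, y, zP + side * 0.8),
                 c(x - 0.8, y, zP + side * 0.8),
                 c(x, y + 0.5, zP - side * 5),
                 c(x, y - 0.5, zP - side * 10))
    add_atoms(c("P", "O", "O", "C", "C"), xyz, "lipid", lid,
              c(TRUE, TRUE, TRUE, FALSE, FALSE),
              name = c("P", "O11", "O12", "C2", "C3"))
    lid
  }

  # a contact lipid anchored to the protein surface at angle `ang`; plants
  # `nhb` ideal H-bond triplets (protein O acceptors are added alongside)
  make_contact_lipid <- function(ang, side, nhb) {
    lid <<- lid + 1L
    zc <- side * leaflet_z * 0.55
    dirv <- c(cos(ang), sin(ang), 0)
    surf <- center + c(prot_radius * dirv[1:2], 0) + c(0, 0, zc)
    # a real protein surface atom at the anchor point, so the planted contact
    # distance is exact for every contact lipid; the anchor is displaced
    # toward the midplane so the contact oxygen stays clear of the planted
    # hydrogen-bond cluster
    anchor <- surf + c(0, 0, -side * 3.2)
    add_atoms("C", matrix(anchor, 1), "protein", NA_integer_, FALSE,
              name = "CAN", planted = TRUE)
    contact_at <- anchor + dirv * contact_distance
    P <- surf + dirv * (contact_distance + 1.5) + c(0, 0, 0.5)
    xyz <- rbind(contact_at, P)
    el <- c("O", "P"); nm <- c("O11", "P")
    hd <- c(TRUE, TRUE); pl <- c(TRUE, FALSE)
    if (nhb > 0L) {
      for (k in seq_len(nhb)) {
        up <- c(0, 0, side * ((k - (nhb + 1) / 2) * 1.6 + 0.8))
        acc <- surf + up                      # protein acceptor O
        don <- acc + dirv * 2.8               # lipid donor O
        hyd <- acc + dirv * 1.8               # H on the D-A line, 1.0 from donor
        add_atoms("O", matrix(acc, 1), "protein", NA_integer_, FALSE,
                  name = "OAC", planted = TRUE)
        xyz <- rbind(xyz, don, hyd)
        el <- c(el, "O", "H"); nm <- c(nm, sprintf("OD%d", k), sprintf("HD%d", k))
        hd <- c(hd, TRUE, TRUE); pl <- c(pl, TRUE, TRUE)
      }
    }
    # tails pointing to the midplane
    xyz <- rbind(xyz, P + c(0, 0, -side * 6), P + c(0, 0, -side * 11))
    el <- c(el, "C", "C"); nm <- c(nm, "C2", "C3")
    hd <- c(hd, FALSE, FALSE); pl <- c(pl, FALSE, FALSE)
    add_atoms(el, xyz, "lipid", lid, hd, name = nm, planted = pl)
    lid
  }

  # planted persistent shell
  shell_ids <- integer(0); shell_leaflet <- character(0)
  sides <- c(rep(-1, shell_split[1]), rep(1, shell_split[2]))
  angs <- seq(0, 2 * pi, length.out = n_shell + 1L)[-1]
  for (i in seq_len(n_shell)) {
    shell_ids <- c(shell_ids, make_contact_lipid(angs[i], sides[i],
                                                 hbonds_per_lipid))
    shell_leaflet <- c(shell_leaflet, if (sides[i] > 0) "upper" else "lower")
  }

  # transient lipids: same construction, no H-bonds; contact only in a
  # planted fraction of frames (they are displaced outward otherwise)
  transient_ids <- integer(0)
  t_angs <- angs + pi / n_shell
  for (i in seq_len(n_transient)) {
    transient_ids <- c(transient_ids,
                       make_contact_lipid(t_angs[(i - 1L) %% n_shell + 1L],
                                          sample(c(-1, 1), 1), 0L))
  }

  # bulk lipids on a jittered grid, kept off the protein
  bulk_ids <- integer(0)
  if (n_lipids > 0L) {
    per_leaf <- ceiling(n_lipids / 2)
    spots <- function(n) {
      nx <- ceiling(sqrt(n * box[1] / box[2]))
      ny <- ceiling(n / nx)
      g <- expand.grid(x = seq(4, box[1] - 4, length.out = nx),
                       y = seq(4, box[2] - 4, length.out = ny))
      g[seq_len(min(n, nrow(g))), ]
    }
    for (side in c(-1, 1)) {
      g <- spots(if (side < 0) per_leaf else n_lipids - per_leaf)
      keep <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2) >
        prot_radius + 6
      g <- g[keep, , drop = FALSE]
      for (i in seq_len(nrow(g)))
        bulk_ids <- c(bulk_ids, make_bulk_lipid(g$x[i], g$y[i], side))
      # sample the depression floor: one lipid per leaflet at its center,
      # so the planted minimum is observable at any lipid density
      if (!is.null(depression))
        bulk_ids <- c(bulk_ids, make_bulk_lipid(depression$center[1],
                                                depression$center[2], side))
    }
  }

  # planted heavy clashes: one atom at 0.3 A from a protein atom
  clash_ids <- integer(0)
  if (n_clashes > 0L) {
    for (i in seq_len(n_clashes)) {
      lid <- lid + 1L
      pa <- as.numeric(prot_xyz[sample(nrow(prot_xyz), 1), ])
      xyz <- rbind(pa + c(0.3, 0, 0), pa + c(3, 0, 0), pa + c(4, 0, 0))
      add_atoms(c("P", "O", "C"), xyz, "lipid", lid, c(TRUE, TRUE, FALSE),
                name = c("P", "O11", "C2"), planted = TRUE)
      clash_ids <- c(clash_ids, lid)
    }
  }

  top <- do.call(rbind, atoms)
  xyz0 <- do.call(rbind, coords0)
  top$element <- as.character(top$element)
  sm <- structure_model(top$element, xyz0[, 1], xyz0[, 2], xyz0[, 3],
                        chain = ifelse(top$molecule == "protein", "A", "L"),
                        resid = ifelse(is.na(top$lipid_id), 1L, top$lipid_id),
                        resname = ifelse(top$molecule == "protein", "PRO", "POP"),
                        atom_name = top$atom_name, label = "gen_membrane")
  sm$molecule <- top$molecule
  sm$lipid_id <- top$lipid_id
  sm$headgroup <- top$headgroup

  jit_ok <- !top$planted
  # transient lipids sit out of contact in a deterministic pattern of frames
  trans_contact_frames <- lapply(transient_ids, function(id) {
    k <- round(transient_occupancy * n_frames)
    if (k <= 0) integer(0) else
      sort(sample(n_frames, k))
  })
  frames <- lapply(seq_len(n_frames), function(f) {
    co <- xyz0
    co[jit_ok, ] <- co[jit_ok, ] + matrix(rnorm(sum(jit_ok) * 3, 0, jitter),
                                          ncol = 3)
    for (ti in seq_along(transient_ids)) {
      if (!(f %in% trans_contact_frames[[ti]])) {
        rows <- which(top$lipid_id == transient_ids[ti] &
                        top$molecule == "lipid")
        dirv <- co[rows[1], ] - c(center[1], center[2], co[rows[1], 3])
        dirv[3] <- 0; dirv <- dirv / sqrt(sum(dirv^2))
        co[rows, ] <- co[rows, ] + matrix(dirv * 8, length(rows), 3,
                                          byrow = TRUE)
      }
    }
    co
  })
  traj <- trajectory(sm, frames, box = box,
                     time = 0.1 * seq_len(n_frames))
  truth <- ground_truth("gen_membrane", seed, list(
    shell_ids = shell_ids, shell_leaflet = shell_leaflet,
    shell_split = shell_split, transient_ids = transient_ids,
    transient_occupancy = vapply(trans_contact_frames, length, numeric(1)) /
      n_frames,
    bulk_ids = bulk_ids, clash_ids = clash_ids,
    hbonds_per_lipid = hbonds_per_lipid,
    bulk_thickness = 2 * leaflet_z,
    depression = depression, box = box, n_frames = n_frames,
    contact_distance = contact_distance))
  list(trajectory = traj, truth = truth)
}

#' Generate a toy structure with known collision cross-section
#'
#' @param kind `"sphere_cluster"` (n atoms in a ball), `"diatomic"` (two
#'   atoms at distance `d`), or `"bundle"` (a helical bundle of pseudo-atoms).
#' @param n atoms (sphere_cluster).
#' @param radius atom radius (A).
#' @param d center separation (diatomic).
#' @param spread cluster ball radius (sphere_cluster).
#' @param seed RNG seed.
#' @return list with `structure` (a [structure_model()]) and `truth`
#'   (for `n = 1` and `diatomic`, the analytic/oracle-ready parameters).
#' @export
gen_toy_structure <- function(kind = c("sphere_cluster", "diatomic", "bundle"),
                              n = 1L, radius = 2.0, d = 5.0, spread = 10,
                              seed = 1L) {
  kind <- match.arg(kind)
  .seed_guard(seed)
  xyz <- switch(kind,
    sphere_cluster = if (n == 1L) matrix(0, 1, 3) else
      matrix(runif(n * 3, -spread, spread), ncol = 3),
    diatomic = rbind(c(0, 0, 0), c(d, 0, 0)),
    bundle = {
      t <- seq(0, 6 * pi, length.out = 120)
      do.call(rbind, lapply(c(0, pi / 2, pi, 3 * pi / 2), function(ph)
        cbind(8 * cos(t / 3 + ph), 8 * sin(t / 3 + ph), seq(-20, 20,
                                                            length.out = 120))))
    })
  s <- structure_model("C", xyz[, 1], xyz[, 2], xyz[, 3], radius = radius,
                       label = paste0("toy_", kind))
  truth <- ground_truth("gen_toy_structure", seed, list(
    kind = kind, n = nrow(xyz), radius = radius,
    d = if (kind == "diatomic") d else NULL))
  list(structure = s, truth = truth)
}
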