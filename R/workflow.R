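# End-to-end demonstration workflows on synthetic data.  Each workflow takes
# a config list (fully serializable; the report embeds it), runs generator ->
# analysis, and returns a structured report that can be written as JSON.

default_ms_config <- function() {
  list(seed = 1L, scenario = "stable_dimer",
       base_mass = 41225, adduct_mass = 1430.98,
       charge_range = c(10L, 13L), lambda = 1.5, snr = 100,
       concentrations = c(0.5, 1, 2, 4, 8, 16),
       dissociation_voltages = seq(20, 200, by = 20),
       cv50 = c(PG = 140, PE = 110, MAG = 60))
}

#' Run the native-MS workflow on synthetic spectra
#'
#' Generates spectra for the configured scenario, deconvolves them, profiles
#' lipid adducts, classifies a titration and ranks lipid gas-phase
#' stabilities by CV50.
#'
#' @param config list; see the defaults in the source.  `scenario` is
#'   `"stable_dimer"` (dimer, no lipids), `"weak_dimer_cdl"` (monomer with a
#'   CDL adduct ladder) or `"titration"`.
#' @return a `workflow_report` list with a `species_table`, `adduct_profile`,
#'   `titration`, `cv50_ranking`, and the embedded `config`.
#' @export
run_ms_workflow <- function(config = list()) {
  cfg <- utils::modifyList(default_ms_config(), config)
  seed <- cfg$seed
  report <- list(config = cfg)

  if (identical(cfg$stages, list())) {
    report$note <- "no stages requested"
    return(structure(report, class = "workflow_report"))
  }

  dimer <- species_model(cfg$base_mass, 2L, cfg$adduct_mass,
                         max_adducts = if (cfg$scenario == "stable_dimer") 0L else 6L,
                         charge_range = cfg$charge_range, label = "dimer")
  monomer <- species_model(cfg$base_mass, 1L, cfg$adduct_mass, max_adducts = 6L,
                           charge_range = c(7L, 10L), label = "monomer")
  if (cfg$scenario == "stable_dimer") {
    gen <- gen_spectrum(list(dimer), lambda = 0, snr = cfg$snr,
                        seed = derive_seed(seed, 1))
    dec <- deconvolve(gen$spectrum, list(dimer, monomer))
  } else {
    gen <- gen_spectrum(list(monomer, dimer), abundances = c(0.8, 0.2),
                        lambda = cfg$lambda, snr = cfg$snr,
                        seed = derive_seed(seed, 1))
    dec <- deconvolve(gen$spectrum, list(dimer, monomer))
  }
  dominant <- names(which.max(dec$abundance))
  report$species_table <- data.frame(
    label = names(dec$abundance), abundance = unname(dec$abundance),
    neutral_mass = unname(dec$neutral_mass[names(dec$abundance)]))
  report$dominant_oligomer <- unname(
    dec$assignments$oligomer_state[match(dominant, dec$assignments$label)])
  prof <- adduct_profile(dec, species_label = dominant)
  report$adduct_profile <- prof

  if (cfg$scenario == "weak_dimer_cdl") {
    # acyl-chain ladder: monomer bound to consecutive CDL homologs; the
    # recovered neutral masses should be spaced by ~28 Da per two carbons
    ladder <- lapply(c(68L, 70L, 72L), function(nc)
      species_model(cfg$base_mass +
                      build_species("CDL", nc, 3L)$average_mass,
                    1L, 0, 0L, c(7L, 10L), label = sprintf("mono_CDL%d:3", nc)))
    gl <- gen_spectrum(ladder, abundances = c(0.5, 1, 0.5), snr = cfg$snr,
                       mz_sigma = 0.4, mz_step = 0.1,
                       seed = derive_seed(seed, 2))
    dl <- deconvolve(gl$spectrum, ladder)
    report$adduct_spacing_da <- series_spacing(unname(dl$neutral_mass))
  }

  # titration: mean occupancy grows linearly with concentration (planted
  # non-specific binding)
  dimer_ad <- species_model(cfg$base_mass, 2L, cfg$adduct_mass, 10L,
                            cfg$charge_range, "dimer")
  occ <- vapply(seq_along(cfg$concentrations), function(i) {
    g <- gen_spectrum(list(dimer_ad),
                      lambda = 0.15 * cfg$concentrations[i], snr = cfg$snr,
                      seed = derive_seed(seed, 10 + i))
    adduct_profile(deconvolve(g$spectrum, list(dimer_ad)))$mean
  }, numeric(1))
  report$titration <- titration_analysis(cfg$concentrations, occ)

  # gas-phase dissociation ranking with planted CV50s
  curves <- lapply(names(cfg$cv50), function(nm) {
    v <- cfg$dissociation_voltages
    f <- 1 / (1 + exp((v - cfg$cv50[[nm]]) / 12))
    fit_dissociation(v, f)
  })
  names(curves) <- names(cfg$cv50)
  report$cv50_ranking <- stability_ranking(curves)
  structure(report, class = "workflow_report")
}

default_ciu_config <- function() {
  list(seed = 1L, charge = 11L, mass = 82450,
       energies = seq(400, 2800, by = 100),
       scenarios = list(
         lipid_free = list(compact = 5000, unfolded = 6000, onset = 900,
                           midpoint = 1100, mode = "two_state"),
         one_lipid = list(compact = 5050, unfolded = 6000, onset = 2000,
                          midpoint = 2200, mode = "two_state"),
         two_lipids = list(compact = 5100, unfolded = 6000, onset = 2400,
                           midpoint = 2600, mode = "two_state")),
       snr = 50)
}

#' Run the CIU workflow on synthetic unfolding surfaces
#'
#' Generates a CIU surface per scenario, extracts unfolding metrics and
#' reports pairwise stabilization shifts against the first scenario.
#'
#' @param config list, see the defaults in the source.
#' @return a `workflow_report` with `metrics` per scenario and `shifts`.
#' @export
run_ciu_workflow <- function(config = list()) {
  cfg <- utils::modifyList(default_ciu_config(), config)
  report <- list(config = cfg, metrics = list(), shifts = list())
  results <- list()
  for (i in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[i]]
    g <- gen_ciu(sc$compact, sc$unfolded, sc$onset, sc$midpoint,
                 mode = sc$mode, charge = cfg$charge, mass = cfg$mass,
                 energies = cfg$energies, snr = cfg$snr,
                 seed = derive_seed(cfg$seed, i))
    fp <- build_fingerprint(g$atd, g$cal, cfg$charge, cfg$mass)
    res <- unfolding_metrics(fp)
    results[[names(cfg$scenarios)[i]]] <- res
    report$metrics[[names(cfg$scenarios)[i]]] <- list(
      compact_ccs = res$compact_ccs, unfolded_ccs = res$unfolded_ccs,
      percent_expansion = res$percent_expansion,
      onset_energy = res$onset_energy, midpoint_energy = res$midpoint_energy,
      classification = res$classification,
      planted = sc)
  }
  if (length(results) > 1L) {
    base <- results[[1]]
    for (nm in names(results)[-1])
      report$shifts[[nm]] <- stabilization_shift(base, results[[nm]])
  }
  structure(report, class = "workflow_report")
}

default_traj_config <- function() {
  list(seed = 1L, n_lipids = 120L, n_frames = 8L,
       shell_split = c(10L, 13L), n_transient = 6L,
       occupancy_min = 0.9, contact_cutoff = 2.15,
       density_spacing = 2.0, hbond_d_max = 3.5, hbond_angle_min = 150,
       dx_path = NULL)
}

#' Run the trajectory workflow on a synthetic membrane
#'
#' Generates a planted membrane trajectory, then: aligns frames, removes
#' clashes, detects contacts, selects the annular shell with its leaflet
#' split, computes the phosphate density (optionally written as DX), the
#' thickness map, hydrogen-bond statistics, and CCS with/without the shell
#' lipids.
#'
#' @param config list, see the defaults in the source.
#' @return a `workflow_report`.
#' @export
run_traj_workflow <- function(config = list()) {
  cfg <- utils::modifyList(default_traj_config(), config)
  if (!is.null(cfg$n_frames) && cfg$n_frames < 1L) stop("zero-frame input")
  gen <- gen_membrane(n_lipids = cfg$n_lipids, n_frames = cfg$n_frames,
                      shell_split = cfg$shell_split,
                      n_transient = cfg$n_transient,
                      seed = derive_seed(cfg$seed, 1))
  traj <- align_frames(gen$trajectory)
  cl <- remove_clashing_lipids(traj)
  traj <- cl$trajectory
  contacts <- detect_contacts(traj, cutoff = cfg$contact_cutoff)
  leaf <- assign_leaflets(traj)
  shell <- select_annular_shell(contacts, occupancy_min = cfg$occupancy_min,
                                leaflets = leaf)
  dens <- phosphate_density(traj, contacts, spacing = cfg$density_spacing)
  if (!is.null(cfg$dx_path)) write_dx(dens, cfg$dx_path)
  thick <- thickness_map(traj)
  hb <- count_hbonds(traj, shell$lipid_ids, d_max = cfg$hbond_d_max,
                     angle_min = cfg$hbond_angle_min)

  # CCS of the final frame with and without the shell lipids
  top <- traj$topology
  frame_sm <- top
  frame_sm[, c("x", "y", "z")] <- traj$frames[[n_frames(traj)]]
  keep <- top$molecule == "protein" | top$lipid_id %in% shell$lipid_ids
  coated <- frame_sm[keep, , drop = FALSE]
  class(coated) <- class(traj$topology)
  ccs <- ccs_with_without_ligands(coated, ligand_resnames = "POP",
                                  seed = derive_seed(cfg$seed, 2),
                                  n_rotations = 100L, n_probes = 1000L)
  report <- list(
    config = cfg,
    n_clashes_removed = cl$n_removed,
    shell = shell$table, shell_size = length(shell$lipid_ids),
    shell_per_leaflet = as.list(shell$per_leaflet),
    shell_matches_truth = setequal(shell$lipid_ids,
                                   gen$truth$parameters$shell_ids),
    density_max = max(dens$values),
    density_integral_points = grid_integral(dens),
    thickness_minimum = thick$minimum,
    hbond_mean_per_lipid = hb$mean_per_lipid,
    ccs_full = ccs$ccs_full$ccs,
    ccs_protein_only = ccs$ccs_protein_only$ccs,
    truth = gen$truth)
  structure(report, class = "workflow_report")
}

#' Write a workflow report as JSON
#'
#' @param report a `workflow_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), path)
  invisible(path)
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("workflow_report with entries:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
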