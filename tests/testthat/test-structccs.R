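# Monte-Carlo projection CCS: analytic and oracle agreement, invariances.

test_that("single sphere matches the analytic projected area", {
  s <- structure_model("C", 0, 0, 0, radius = 2)
  est <- pa_ccs(s, probe_radius = 1, n_rotations = 60L, n_probes = 4000L,
                scale_factor = 1, seed = 1)
  expect_equal(est$ccs, pi * 3^2, tolerance = 3 * est$standard_error / est$ccs + 0.01)
  # scale factor is a pure multiplier
  est2 <- pa_ccs(s, probe_radius = 1, n_rotations = 60L, n_probes = 4000L,
                 scale_factor = 1.14, seed = 1)
  expect_equal(est2$ccs, 1.14 * est$ccs, tolerance = 1e-9)
})

test_that("well-separated diatomic equals twice the single-sphere area", {
  g <- gen_toy_structure("diatomic", d = 100, radius = 2, seed = 2)
  est <- pa_ccs(g$structure, probe_radius = 1, n_rotations = 400L,
                n_probes = 10000L, scale_factor = 1, seed = 2)
  expect_equal(est$ccs, 2 * pi * 9, tolerance = 0.02)
})

test_that("overlapping diatomic matches the orientation-grid overlap oracle", {
  # frozen oracle value for d = 5, disk radius 3 (atom 2 + probe 1)
  oracle <- oracle_diatomic_area(5, 3)
  expect_equal(oracle, 49.5557, tolerance = 1e-5)
  g <- gen_toy_structure("diatomic", d = 5, radius = 2, seed = 3)
  est <- pa_ccs(g$structure, probe_radius = 1, n_rotations = 400L,
                n_probes = 4000L, scale_factor = 1, seed = 3)
  expect_equal(est$ccs, oracle, tolerance = 0.005)
})

test_that("CCS is invariant under rigid motion and seeded-reproducible", {
  g <- gen_toy_structure("bundle", seed = 4)
  s <- g$structure
  est1 <- pa_ccs(s, n_rotations = 150L, n_probes = 2000L, seed = 5)
  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% R
  s2 <- structure_model(s$element, xyz[, 1] + 50, xyz[, 2] - 20, xyz[, 3] + 7,
                        radius = s$radius)
  est2 <- pa_ccs(s2, n_rotations = 150L, n_probes = 2000L, seed = 5)
  expect_equal(est1$ccs, est2$ccs,
               tolerance = 4 * (est1$standard_error + est2$standard_error) / est1$ccs)
  # determinism under a fixed seed
  est3 <- pa_ccs(s, n_rotations = 150L, n_probes = 2000L, seed = 5)
  expect_identical(est1$ccs, est3$ccs)
})

test_that("CCS is monotone non-decreasing under atom addition", {
  g <- gen_toy_structure("sphere_cluster", n = 20, spread = 8, seed = 6)
  s <- g$structure
  sub <- s[1:10, ]; class(sub) <- class(s)
  est_sub <- pa_ccs(sub, n_rotations = 200L, n_probes = 3000L, seed = 7)
  est_all <- pa_ccs(s, n_rotations = 200L, n_probes = 3000L, seed = 7)
  expect_gte(est_all$ccs + 3 * (est_all$standard_error + est_sub$standard_error),
             est_sub$ccs)
})

test_that("standard error shrinks ~1/sqrt(N) over a 100x sample sweep", {
  g <- gen_toy_structure("sphere_cluster", n = 12, spread = 6, seed = 8)
  lo <- pa_ccs(g$structure, n_rotations = 30L, n_probes = 500L, seed = 9)
  hi <- pa_ccs(g$structure, n_rotations = 3000L, n_probes = 500L, seed = 9)
  ratio <- lo$standard_error / hi$standard_error
  expect_gt(ratio, 10 / 2)   # expected 10, generous band
  expect_lt(ratio, 10 * 2)
})

test_that("trajectory CCS uses the trailing window and averages conformers", {
  g1 <- gen_toy_structure("sphere_cluster", n = 15, spread = 5, seed = 10)
  s1 <- g1$structure
  xyz <- as.matrix(s1[, c("x", "y", "z")]) * 1.6
  s2 <- structure_model(s1$element, xyz[, 1], xyz[, 2], xyz[, 3],
                        radius = s1$radius)
  # window indexing contract: window 0.5 on 10 frames uses frames 6-10
  frames <- c(rep(list(s1), 5), rep(list(s2), 5))
  res <- trajectory_ccs(frames, window = 0.5, n_rotations = 50L,
                        n_probes = 1000L, seed = 11)
  expect_identical(res$frames_used, 6:10)
  ref2 <- pa_ccs(s2, n_rotations = 50L, n_probes = 1000L, seed = 11)
  expect_equal(res$mean_ccs, ref2$ccs, tolerance = 0.05)
  # alternating conformers: mean is the average of the two
  alt <- rep(list(s1, s2), 5)
  res_alt <- trajectory_ccs(alt, window = 1, n_rotations = 80L,
                            n_probes = 1500L, seed = 12)
  ref1 <- pa_ccs(s1, n_rotations = 400L, n_probes = 1500L, seed = 13)
  ref2b <- pa_ccs(s2, n_rotations = 400L, n_probes = 1500L, seed = 13)
  expect_equal(res_alt$mean_ccs, (ref1$ccs + ref2b$ccs) / 2, tolerance = 0.03)
  # identical frames: s.d. is MC noise only
  same <- trajectory_ccs(rep(list(s1), 4), window = 1, n_rotations = 200L,
                         n_probes = 2000L, seed = 14)
  expect_lt(same$sd_ccs / same$mean_ccs, 0.05)
  expect_error(trajectory_ccs(list(s1), window = 0.5), "at least 2")
  expect_error(trajectory_ccs(frames, window = 0), "window")
})

test_that("ligand-stripped CCS is consistent", {
  gm <- gen_membrane(n_lipids = 0L, n_frames = 2L, shell_split = c(4L, 5L),
                     n_transient = 0L, seed = 15)
  top <- gm$trajectory$topology
  top[, c("x", "y", "z")] <- gm$trajectory$frames[[1]]
  both <- ccs_with_without_ligands(top, ligand_resnames = "POP", seed = 16,
                                   n_rotations = 80L, n_probes = 1500L)
  expect_gt(both$ccs_full$ccs, both$ccs_protein_only$ccs)
  # without ligand atoms both estimates coincide
  prot_only <- select_atoms(top, resname = "POP", invert = TRUE)
  same <- ccs_with_without_ligands(prot_only, ligand_resnames = "POP",
                                   seed = 16, n_rotations = 50L,
                                   n_probes = 1000L)
  expect_identical(same$ccs_full$ccs, same$ccs_protein_only$ccs)
  expect_error(ccs_with_without_ligands(
    select_atoms(top, resname = "POP"), ligand_resnames = "POP", seed = 1),
    "empty protein")
})

test_that("degenerate inputs are rejected", {
  s <- structure_model("C", 0, 0, 0, radius = 2)
  expect_error(pa_ccs(s[0, ]), "no atoms")
  expect_error(pa_ccs(s, probe_radius = -1), "positive")
  expect_error(pa_ccs(s, n_rotations = 0), "sampling")
})

test_that("PDB read/write round-trips single and multi-model structures", {
  g <- gen_toy_structure("bundle", seed = 17)
  s <- g$structure
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$x, s$x, tolerance = 1e-3)
  expect_identical(s2$element, s$element)
  # multi-model
  s_shift <- s; s_shift$z <- s$z + 5
  write_pdb(list(s, s_shift), path, box = c(100, 90, 80))
  multi <- read_pdb(path)
  expect_s3_class(multi, "pdb_trajectory_raw")
  expect_length(multi$models, 2)
  expect_equal(multi$box, c(100, 90, 80))
  expect_equal(multi$models[[2]]$z, s2$z + 5, tolerance = 1e-3)
})
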