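# Alignment, contacts, clash removal, leaflets, shell, density, thickness,
# H-bonds.

test_that("alignment undoes rigid transforms and is idempotent", {
  gm <- gen_membrane(n_lipids = 30L, n_frames = 1L, shell_split = c(2L, 3L),
                     n_transient = 0L, jitter = 0, seed = 31)
  tr <- gm$trajectory
  co <- tr$frames[[1]]
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(co %*% R, 2, c(10, -5, 3), "+")
  tr$frames <- list(co, moved)
  tr$time <- c(0.1, 0.2)
  al <- align_frames(tr)
  expect_lt(max(abs(al$frames[[2]] - co)), 1e-8)
  expect_lt(attr(al, "rmsd")[2], 1e-8)
  # rigidity: inter-atomic distances unchanged by alignment
  d_before <- dist(moved[1:20, ])
  d_after <- dist(al$frames[[2]][1:20, ])
  expect_equal(as.vector(d_after), as.vector(d_before), tolerance = 1e-10)
  # idempotence
  al2 <- align_frames(al)
  expect_lt(max(abs(al2$frames[[2]] - al$frames[[2]])), 1e-8)
  expect_error(align_frames(tr, reference_selection = 1:2), ">= 3")
})

test_that("contact cutoff is inclusive at exactly 2.15 A", {
  mk <- function(dx) {
    frames <- list(rbind(c(0, 0, 0), c(dx, 0, 0), c(dx + 1, 0, 0),
                         c(0, 0, 30), c(1, 0, 30), c(2, 0, 30)))
    toy_trajectory(frames,
                   molecule = c("protein", rep("lipid", 2), "protein",
                                rep("lipid", 2)),
                   lipid_id = c(NA, 1L, 1L, NA, 2L, 2L),
                   element = c("C", "O", "C", "C", "O", "C"),
                   headgroup = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  }
  ct <- detect_contacts(mk(2.15), cutoff = 2.15, lipid_part = "whole")
  expect_true(ct$in_contact[1, "1"])
  ct2 <- detect_contacts(mk(2.16), cutoff = 2.15, lipid_part = "whole")
  expect_false(ct2$in_contact[1, "1"])
  expect_error(detect_contacts(mk(2), cutoff = -1), "positive")
})

test_that("cell-list contact detection equals the brute-force oracle", {
  set.seed(32)
  for (i in 1:50) {
    sys <- random_contact_system(n_prot = sample(10:60, 1),
                                 n_lipids = sample(4:15, 1))
    cutoff <- runif(1, 1, 6)
    n <- nrow(sys$prot) + nrow(sys$lip)
    frames <- list(rbind(sys$prot, sys$lip))
    tr <- toy_trajectory(frames,
                         molecule = c(rep("protein", nrow(sys$prot)),
                                      rep("lipid", nrow(sys$lip))),
                         lipid_id = c(rep(NA_integer_, nrow(sys$prot)),
                                      sys$lipid_id),
                         element = rep("C", n),
                         headgroup = c(rep(FALSE, nrow(sys$prot)),
                                       rep(TRUE, nrow(sys$lip))))
    ct <- detect_contacts(tr, cutoff = cutoff, lipid_part = "whole")
    got <- as.integer(colnames(ct$in_contact)[ct$in_contact[1, ]])
    expect_identical(got, oracle_contacts(sys$prot, sys$lip, sys$lipid_id,
                                          cutoff))
  }
})

test_that("occupancy equals contact-frame fraction", {
  gm <- gen_membrane(n_lipids = 20L, n_frames = 8L, shell_split = c(2L, 2L),
                     n_transient = 4L, transient_occupancy = 0.5, seed = 33)
  ct <- detect_contacts(gm$trajectory)
  tp <- gm$truth$parameters
  expect_equal(unname(ct$occupancy[as.character(tp$shell_ids)]),
               rep(1, 4))
  expect_equal(unname(ct$occupancy[as.character(tp$transient_ids)]),
               tp$transient_occupancy)
  expect_equal(unname(ct$occupancy[as.character(tp$bulk_ids)]),
               rep(0, length(tp$bulk_ids)))
  # zero jitter: identical contact sets in every frame
  gm0 <- gen_membrane(n_lipids = 10L, n_frames = 4L, shell_split = c(2L, 2L),
                      n_transient = 0L, jitter = 0, seed = 34)
  ct0 <- detect_contacts(gm0$trajectory)
  expect_true(all(apply(ct0$in_contact, 2, function(col) length(unique(col)) == 1)))
})

test_that("clash removal removes exactly the planted clashing lipids", {
  gm <- gen_membrane(n_lipids = 25L, n_frames = 2L, shell_split = c(2L, 2L),
                     n_transient = 0L, n_clashes = 3L, seed = 35)
  res <- remove_clashing_lipids(gm$trajectory)
  expect_identical(sort(res$removed_ids), sort(gm$truth$parameters$clash_ids))
  expect_identical(res$n_removed, 3L)
  # no clash: nothing removed
  gm2 <- gen_membrane(n_lipids = 10L, n_frames = 1L, shell_split = c(1L, 1L),
                      n_transient = 0L, seed = 36)
  expect_identical(remove_clashing_lipids(gm2$trajectory)$n_removed, 0L)
})

test_that("leaflet assignment recovers flat bilayers and breaks ties", {
  z <- c(rep(20, 5), rep(-20, 5))
  n <- 10L
  frames <- list(cbind(seq_len(n) * 5, rep(1, n), z))
  tr <- toy_trajectory(frames, molecule = rep("lipid", n),
                       lipid_id = seq_len(n), element = rep("P", n))
  lf <- assign_leaflets(tr)
  expect_identical(unname(lf[as.character(1:5)]), rep("upper", 5))
  expect_identical(unname(lf[as.character(6:10)]), rep("lower", 5))
  # midplane lipid: tie goes to the nearer leaflet mean
  z2 <- c(rep(20, 3), rep(-10, 3), 5)
  frames2 <- list(cbind(seq_len(7) * 5, rep(1, 7), z2))
  tr2 <- toy_trajectory(frames2, molecule = rep("lipid", 7),
                        lipid_id = 1:7, element = rep("P", 7))
  lf2 <- assign_leaflets(tr2)
  # exactly at the midplane, equidistant from both centroids: documented
  # tie rule assigns "upper"
  expect_identical(unname(lf2["7"]), "upper")
  expect_error(assign_leaflets(toy_trajectory(
    list(matrix(0, 1, 3)), "lipid", 1L, "P")), "at least 2")
})

test_that("planted 23-lipid shell with a 10/13 leaflet split is recovered", {
  gm <- gen_membrane(n_lipids = 120L, n_frames = 6L, seed = 37)
  tr <- align_frames(gm$trajectory)
  ct <- detect_contacts(tr)
  lf <- assign_leaflets(tr)
  sh <- select_annular_shell(ct, occupancy_min = 0.9, leaflets = lf)
  tp <- gm$truth$parameters
  expect_identical(sort(sh$lipid_ids), sort(tp$shell_ids))
  expect_identical(as.integer(sh$per_leaflet[c("lower", "upper")]),
                   c(10L, 13L))
  # occupancy_min = 0 selects every ever-contacting lipid
  all_sel <- select_annular_shell(ct, occupancy_min = 0)
  expect_true(all(tp$transient_ids %in% all_sel$lipid_ids))
  # impossible threshold: empty set allowed
  none <- select_annular_shell(ct, occupancy_min = 1.01)
  expect_length(none$lipid_ids, 0)
})

test_that("KDE conserves mass and localizes planted clusters", {
  set.seed(38)
  # single point
  g1 <- kde3d_grid(matrix(c(1, 2, 3), 1), bandwidth = 1.5, spacing = 0.75)
  expect_equal(grid_integral(g1), 1, tolerance = 0.01)
  am <- arrayInd(which.max(g1$values), dim(g1$values))
  peak <- g1$origin + (as.vector(am) - 1) * g1$spacing
  expect_lt(sqrt(sum((peak - c(1, 2, 3))^2)), 0.75 * sqrt(3) + 1e-9)
  # N points, multiple bandwidth/spacing combinations
  for (bw in c(0.8, 2)) for (sp in c(0.6, 1.2)) {
    pts <- matrix(rnorm(3 * 40, sd = 4), ncol = 3)
    g <- kde3d_grid(pts, bandwidth = bw, spacing = sp)
    expect_equal(grid_integral(g), 40, tolerance = 0.01)
  }
  # planted cluster center within one bandwidth
  ctr <- c(10, -4, 6)
  pts <- sweep(matrix(rnorm(3 * 60, sd = 1), ncol = 3), 2, ctr, "+")
  g <- kde3d_grid(pts, spacing = 0.8)
  am <- arrayInd(which.max(g$values), dim(g$values))
  peak <- g$origin + (as.vector(am) - 1) * g$spacing
  expect_lt(sqrt(sum((peak - ctr)^2)), max(g$bandwidth) + g$spacing)
  expect_error(kde3d_grid(matrix(0, 0, 3)), "nrow")
})

test_that("phosphate density integrates to the number of contact events", {
  gm <- gen_membrane(n_lipids = 40L, n_frames = 5L, shell_split = c(3L, 4L),
                     n_transient = 2L, seed = 39)
  tr <- align_frames(gm$trajectory)
  ct <- detect_contacts(tr)
  dg <- phosphate_density(tr, ct, spacing = 1.5)
  expect_equal(grid_integral(dg), sum(ct$in_contact), tolerance = 0.01)
  expect_true(all(dg$values >= 0))
})

test_that("density thresholding labels 26-connected components", {
  # two well-separated planted clusters
  pts <- rbind(matrix(rnorm(3 * 30, sd = 1), ncol = 3),
               sweep(matrix(rnorm(3 * 30, sd = 1), ncol = 3), 2,
                     c(25, 0, 0), "+"))
  g <- kde3d_grid(pts, bandwidth = 1.2, spacing = 1)
  th <- threshold_density(g, cutoff = 1)  # nm^-3
  expect_identical(th$n_components, 2L)
  expect_length(th$volumes, 2)
  expect_true(!is.unsorted(rev(th$volumes)))
  # cutoff above max: empty mask
  th_hi <- threshold_density(g, cutoff = max(g$values) * 1.1)
  expect_identical(th_hi$n_components, 0L)
  expect_false(any(th_hi$mask))
  # cutoff 0 covers everything
  th0 <- threshold_density(g, cutoff = 0)
  expect_true(all(th0$mask))
})

test_that("DX export round-trips the grid", {
  pts <- matrix(rnorm(3 * 20), ncol = 3)
  g <- kde3d_grid(pts, bandwidth = 1, spacing = 1)
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  g2 <- read_dx(path)
  expect_equal(dim(g2$values), dim(g$values))
  expect_equal(g2$origin, g$origin, tolerance = 1e-5)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
})

test_that("thickness map recovers flat and depressed bilayers", {
  gm <- gen_membrane(n_lipids = 80L, n_frames = 3L, shell_split = c(0L, 0L),
                     n_transient = 0L, jitter = 0, seed = 40)
  tm <- thickness_map(gm$trajectory)
  expect_equal(min(tm$thickness, na.rm = TRUE), 38, tolerance = 1e-9)
  expect_equal(max(tm$thickness, na.rm = TRUE), 38, tolerance = 1e-9)
  # planted depression: minimum at the planted center within one cell
  dep <- list(center = c(30, 40), depth = 8, sigma = 15)
  gm2 <- gen_membrane(n_lipids = 80L, n_frames = 4L, shell_split = c(0L, 0L),
                      n_transient = 0L, depression = dep, seed = 41)
  tm2 <- thickness_map(align_frames(gm2$trajectory))
  expect_equal(tm2$minimum$thickness, 30, tolerance = 0.5 / 30)
  expect_lte(abs(tm2$minimum$x - 30), tm2$grid_spacing)
  expect_lte(abs(tm2$minimum$y - 40), tm2$grid_spacing)
  # uncovered cells are NA, never zero
  expect_false(any(tm2$thickness == 0, na.rm = TRUE))
})

test_that("thickness map is invariant under periodic xy translation", {
  gm <- gen_membrane(n_lipids = 60L, n_frames = 2L, shell_split = c(0L, 0L),
                     n_transient = 0L, jitter = 0, seed = 42)
  tr <- gm$trajectory
  tm1 <- thickness_map(tr, grid_spacing = 5)
  shift <- c(3 * 5, 2 * 5)  # whole cells
  box <- tr$box[1, ]
  tr2 <- tr
  tr2$frames <- lapply(tr$frames, function(f) {
    f[, 1] <- (f[, 1] + shift[1])
    f[, 2] <- (f[, 2] + shift[2])
    f
  })
  tm2 <- thickness_map(tr2, grid_spacing = 5)
  v1 <- sort(round(as.vector(tm1$thickness[!is.na(tm1$thickness)]), 6))
  v2 <- sort(round(as.vector(tm2$thickness[!is.na(tm2$thickness)]), 6))
  expect_equal(v1, v2)
  expect_equal(min(tm1$thickness, na.rm = TRUE),
               min(tm2$thickness, na.rm = TRUE))
})

test_that("hydrogen bonds: planted ideal geometries are counted exactly", {
  gm <- gen_membrane(n_lipids = 30L, n_frames = 4L, shell_split = c(3L, 3L),
                     n_transient = 0L, hbonds_per_lipid = 3L, seed = 43)
  tr <- gm$trajectory
  sh_ids <- gm$truth$parameters$shell_ids
  hb <- count_hbonds(tr, sh_ids)
  expect_equal(hb$mean_per_lipid, 3)
  expect_equal(unname(hb$per_lipid_mean), rep(3, length(sh_ids)))
  expect_true(all(hb$bonds$distance <= 3.5))
  expect_true(all(hb$bonds$angle >= 150))
})

test_that("hydrogen-bond geometric criterion boundaries", {
  # ideal planted geometry: D at 2.8 from A, H colinear
  mk <- function(da, hshift = 0) {
    frames <- list(rbind(
      c(0, 0, 0),          # protein acceptor O
      c(da, 0, 0),         # lipid donor O
      c(da - 1, hshift, 0),  # H
      c(da + 2, 0, 0)))    # lipid P (so the phosphorus invariant holds)
    toy_trajectory(frames, molecule = c("protein", "lipid", "lipid", "lipid"),
                   lipid_id = c(NA, 1L, 1L, 1L),
                   element = c("O", "O", "H", "P"))
  }
  expect_equal(count_hbonds(mk(2.8), shell = 1L)$mean_per_lipid, 1)
  # too long at default 3.5
  expect_equal(count_hbonds(mk(4.0), shell = 1L)$mean_per_lipid, 0)
  # bent below the angle threshold (H still within 1.25 A of its donor)
  expect_equal(count_hbonds(mk(2.8, hshift = 0.5), shell = 1L)$mean_per_lipid, 0)
  expect_error(count_hbonds(mk(2.8), shell = integer(0)), "empty")
})

test_that("trajectory container validates invariants", {
  sm <- structure_model("P", 1:2, 1:2, c(-10, 10))
  sm$molecule <- "lipid"; sm$lipid_id <- 1:2
  expect_error(trajectory(sm, list(matrix(0, 3, 3))), "matching the topology")
  expect_error(trajectory(sm, list(matrix(0, 2, 3), matrix(0, 2, 3)),
                          time = c(2, 1)), "strictly increasing")
  two_p <- structure_model("P", 1:2, 1:2, 1:2)
  two_p$molecule <- "lipid"; two_p$lipid_id <- c(1L, 1L)
  expect_error(trajectory(two_p, list(matrix(0, 2, 3))),
               "more than one phosphorus")
})
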