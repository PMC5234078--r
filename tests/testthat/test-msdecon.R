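# Deconvolution, adduct profiling, titration and dissociation analysis.

test_that("mass_spectrum validates its invariants", {
  expect_error(mass_spectrum(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(mass_spectrum(c(2, 1), c(1, 1)), "increasing")
  expect_error(mass_spectrum(c(1, 2), c(-1, 1)), "non-negative")
})

test_that("synthetic dimer deconvolution recovers the neutral mass", {
  dimer <- species_model(41225, 2L, charge_range = c(10L, 13L), label = "dimer")
  g <- gen_spectrum(list(dimer), seed = 11)
  d <- deconvolve(g$spectrum, list(dimer))
  expect_equal(unname(d$neutral_mass["dimer"]), 82450, tolerance = 5 / 82450)
  expect_true(all(abs(d$assignments$ppm_error) <= 200))
})

test_that("exact theoretical peak gives zero ppm error", {
  sp <- species_model(50000, 1L, charge_range = c(10L, 10L))
  mz0 <- (50000 + 10 * 1.00728) / 10
  mz <- seq(mz0 - 20, mz0 + 20, by = 0.05)
  s <- mass_spectrum(mz, dnorm(mz, mz0, 1.5))
  d <- deconvolve(s, list(sp))
  expect_equal(nrow(d$assignments), 1L)
  expect_lt(abs(d$assignments$ppm_error), 1)
})

test_that("mixture abundances are recovered and conserved", {
  dimer <- species_model(41225, 2L, charge_range = c(10L, 13L), label = "dimer")
  mono <- species_model(41225, 1L, charge_range = c(7L, 9L), label = "mono")
  g <- gen_spectrum(list(mono, dimer), abundances = c(30, 70), seed = 12)
  d <- deconvolve(g$spectrum, list(mono, dimer))
  frac <- 100 * d$abundance / sum(d$abundance)
  expect_equal(unname(frac["mono"]), 30, tolerance = 2 / 30)
  expect_equal(unname(frac["dimer"]), 70, tolerance = 2 / 70)
  # abundance conservation against the total ion current
  expect_lte(sum(d$abundance), sum(g$spectrum$intensity))
})

test_that("deconvolution round-trips masses within 100 ppm at SNR >= 20", {
  set.seed(13)
  for (i in 1:5) {
    mass <- runif(1, 3e4, 1.2e5)
    sp <- species_model(mass, 1L, charge_range = c(12L, 16L), label = "s")
    g <- gen_spectrum(list(sp), snr = 20, seed = 100 + i)
    d <- deconvolve(g$spectrum, list(sp))
    expect_gte(nrow(d$assignments), 3)
    expect_lt(abs(d$neutral_mass[["s"]] - mass) / mass * 1e6, 100)
  }
})

test_that("empty and noise-only spectra are handled", {
  sp <- species_model(50000, 1L)
  expect_error(deconvolve(mass_spectrum(numeric(0), numeric(0)), list(sp)),
               "empty spectrum")
  flat <- mass_spectrum(seq(1000, 2000, 1), rep(1, 1001))
  expect_warning(d <- deconvolve(flat, list(sp)), "no peak")
  expect_identical(nrow(d$assignments), 0L)
})

test_that("adduct profile recovers planted Poisson occupancy", {
  sp <- species_model(82450, 1L, adduct_mass = 718, max_adducts = 10L,
                      charge_range = c(10L, 13L), label = "dim")
  g <- gen_spectrum(list(sp), lambda = 1.5, seed = 14)
  prof <- adduct_profile(deconvolve(g$spectrum, list(sp)))
  expect_equal(prof$mean, 1.5, tolerance = 0.1 / 1.5)
  # trivial cases
  p0 <- adduct_profile(data.frame(label = "x", oligomer_state = 1L,
                                  charge = 10L, n_adducts = 0L,
                                  theoretical_mz = 1, matched_mz = 1,
                                  matched_intensity = 5, ppm_error = 0))
  expect_equal(p0$mean, 0)
  p2 <- adduct_profile(data.frame(label = "x", oligomer_state = 1L,
                                  charge = 10L, n_adducts = c(1L, 3L),
                                  theoretical_mz = 1:2, matched_mz = 1:2,
                                  matched_intensity = c(5, 5), ppm_error = 0))
  expect_equal(p2$mean, 2)
  expect_error(adduct_profile(lipidims:::empty_assignments()), "no assignments")
})

test_that("titration classification separates specific from non-specific", {
  conc <- c(0.1, 0.3, 1, 3, 10)
  sat <- titration_analysis(conc, conc / (1 + conc))
  expect_identical(sat$classification, "saturating")
  expect_equal(sat$parameters$Kd, 1, tolerance = 0.1)
  lin <- titration_analysis(conc, 0.25 * conc)
  expect_identical(lin$classification, "non_saturating")
  zero <- titration_analysis(conc, rep(0, 5))
  expect_identical(zero$classification, "non_saturating")
  expect_equal(zero$parameters$slope, 0, tolerance = 1e-10)
  expect_error(titration_analysis(c(1, 1, 1, 1), 1:4), "degenerate")
  expect_error(titration_analysis(1:3, 1:3), "at least 4")
})

test_that("dissociation curve recovers CV50 and handles censoring", {
  v <- seq(20, 200, by = 15)
  f <- 1 / (1 + exp((v - 120) / 10))
  fit <- fit_dissociation(v, f)
  expect_false(fit$censored)
  expect_equal(fit$cv50, 120, tolerance = 3 / 120)
  # censored: never dissociates in range
  cens <- fit_dissociation(v, rep(1, length(v)))
  expect_true(cens$censored)
  expect_equal(cens$cv50[1], 200)
  expect_identical(cens$cv50[2], Inf)
  # non-monotonic flagged but fit returned
  fnm <- f; fnm[9] <- fnm[8] + 0.3
  expect_warning(fitnm <- fit_dissociation(v, fnm), "non-monotonic")
  expect_true(is.numeric(fitnm$cv50))
})

test_that("CV50 from spectra is invariant under uniform intensity rescaling", {
  sp <- species_model(82450, 1L, adduct_mass = 749, max_adducts = 1L,
                      charge_range = c(11L, 12L), label = "c")
  voltages <- seq(40, 200, by = 20)
  make_spectra <- function(scale) lapply(voltages, function(v) {
    bound <- 1 / (1 + exp((v - 120) / 12))
    # construct deterministically: two charge states, bound/free peaks
    mzs <- c(lipidims:::theoretical_mz(sp, 11, 0), lipidims:::theoretical_mz(sp, 11, 1),
             lipidims:::theoretical_mz(sp, 12, 0), lipidims:::theoretical_mz(sp, 12, 1))
    grid <- seq(min(mzs) - 30, max(mzs) + 30, by = 0.25)
    intens <- (1 - bound) * dnorm(grid, mzs[1], 2) + bound * dnorm(grid, mzs[2], 2) +
      (1 - bound) * dnorm(grid, mzs[3], 2) + bound * dnorm(grid, mzs[4], 2)
    mass_spectrum(grid, scale * intens, collision_voltage = v)
  })
  c1 <- dissociation_curve(make_spectra(1), sp)
  c2 <- dissociation_curve(make_spectra(37.5), sp)
  expect_equal(c1$cv50, c2$cv50, tolerance = 1e-8)
  expect_equal(c1$cv50, 120, tolerance = 3 / 120)
  expect_true(all(c1$y >= 0 & c1$y <= 1))
})

test_that("stability ranking orders lipids by CV50, PG > PE > MAG style", {
  v <- seq(20, 200, by = 15)
  curves <- lapply(c(PG = 140, PE = 110, MAG = 60), function(m)
    fit_dissociation(v, 1 / (1 + exp((v - m) / 10))))
  r <- stability_ranking(curves)
  expect_identical(r$lipid, c("PG", "PE", "MAG"))
})

test_that("spectrum text IO round-trips data and metadata", {
  s <- mass_spectrum(seq(2000, 2010, 0.5), runif(21), collision_voltage = 75,
                     lipid_concentration = 2.5, label = "t1")
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$mz, s$mz)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-6)
  expect_equal(s2$metadata$collision_voltage, 75)
  expect_equal(s2$metadata$lipid_concentration, 2.5)
  expect_identical(s2$metadata$label, "t1")
})
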