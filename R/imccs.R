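# Traveling-wave ion-mobility CCS calibration and collision-induced unfolding
# (CIU) quantification.
#
# Calibration chain (the standard TWIMS protocol):
#   t'  = t_A - edc * sqrt(m/z) / 1000        (dead-time correction, ms)
#   W'  = W * sqrt(mu) / z                    (charge/reduced-mass correction)
#   mu  = m * M_gas / (m + M_gas)             (drift gas N2, 28.0134 Da)
# and a log-log linear fit W' = A * t'^B.  Applying the calibration inverts
# the chain: W = A * t'^B * z / sqrt(mu).
#
# CIU fingerprints are intensity over (lab-frame energy x CCS); lab-frame
# energy = charge x trap collision voltage (eV).  Each energy column is
# normalized to unit sum.

#' Fit a traveling-wave CCS calibration
#'
#' @param calibrants data frame with columns `name`, `charge`,
#'   `reference_ccs` (A^2), `arrival_time` (ms), `mass` (Da).
#' @param edc dead-time coefficient; dead time (ms) = `edc * sqrt(m/z) / 1000`.
#' @param gas_mass drift-gas mass (Da), default N2.
#' @return a `ccs_calibration` with power-law coefficients `A`, `B` and
#'   per-calibrant relative residuals.
#' @export
fit_calibration <- function(calibrants, edc = 1.41, gas_mass = N2_MASS) {
  req <- c("charge", "reference_ccs", "arrival_time", "mass")
  if (!all(req %in% names(calibrants))) stop("calibrants must have columns: ",
                                             paste(req, collapse = ", "))
  if (nrow(calibrants) < 3L) stop("need at least 3 calibrant points")
  if (any(calibrants$arrival_time <= 0)) stop("non-positive arrival times")
  mz <- (calibrants$mass + calibrants$charge * PROTON_MASS) / calibrants$charge
  tp <- calibrants$arrival_time - edc * sqrt(mz) / 1000
  if (any(tp <= 0)) stop("arrival time at or below the dead time")
  mu <- calibrants$mass * gas_mass / (calibrants$mass + gas_mass)
  wp <- calibrants$reference_ccs * sqrt(mu) / calibrants$charge
  fit <- lm(log(wp) ~ log(tp))
  A <- exp(unname(coef(fit)[1])); B <- unname(coef(fit)[2])
  pred <- A * tp^B
  structure(list(calibrants = calibrants, A = A, B = B, edc = edc,
                 gas_mass = gas_mass,
                 relative_residuals = (wp - pred) / wp),
            class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("ccs_calibration: W' = %.4g * t'^%.4g (%d calibrants, max |rel res| %.2g)\n",
              x$A, x$B, nrow(x$calibrants), max(abs(x$relative_residuals))))
  invisible(x)
}

#' Convert arrival time to CCS with a fitted calibration
#'
#' @param cal a `ccs_calibration`.
#' @param arrival_time arrival time(s), ms.
#' @param charge charge state.
#' @param mass ion mass (Da).
#' @return CCS in A^2 (vectorized over `arrival_time`).
#' @export
apply_calibration <- function(cal, arrival_time, charge, mass) {
  stopifnot(inherits(cal, "ccs_calibration"))
  mz <- (mass + charge * PROTON_MASS) / charge
  tp <- arrival_time - cal$edc * sqrt(mz) / 1000
  if (any(tp <= 0)) stop("arrival time at or below the dead time")
  mu <- mass * cal$gas_mass / (mass + cal$gas_mass)
  cal$A * tp^cal$B * charge / sqrt(mu)
}

#' Invert a calibration: CCS to arrival time
#'
#' Used by the synthetic generator to render CCS-space populations into
#' arrival-time space.
#'
#' @inheritParams apply_calibration
#' @param ccs CCS value(s), A^2.
#' @export
invert_calibration <- function(cal, ccs, charge, mass) {
  stopifnot(inherits(cal, "ccs_calibration"))
  mz <- (mass + charge * PROTON_MASS) / charge
  mu <- mass * cal$gas_mass / (mass + cal$gas_mass)
  wp <- ccs * sqrt(mu) / charge
  (wp / cal$A)^(1 / cal$B) + cal$edc * sqrt(mz) / 1000
}

#' Assemble a CIU fingerprint from per-voltage arrival-time distributions
#'
#' @param atd ATD stack: list with `arrival_time` (ms), `voltage` (V),
#'   `intensity` matrix (rows = times, cols = voltages); see
#'   [read_atd_stack()].
#' @param cal a `ccs_calibration`.
#' @param charge charge state of the monitored ion.
#' @param mass ion mass (Da).
#' @return a `ciu_fingerprint`: `energy_axis` (eV, = charge x voltage),
#'   `ccs_axis` (A^2, strictly increasing), `intensity` (columns normalized
#'   to unit sum; all-zero columns flagged in `empty_columns`), `charge`.
#' @export
build_fingerprint <- function(atd, cal, charge, mass) {
  if (length(atd$voltage) < 3L) stop("need ATDs at >= 3 collision voltages")
  if (nrow(atd$intensity) != length(atd$arrival_time) ||
      ncol(atd$intensity) != length(atd$voltage))
    stop("intensity matrix does not match the arrival-time/voltage axes")
  if (any(diff(atd$arrival_time) <= 0)) stop("arrival times must be increasing")
  ccs <- apply_calibration(cal, atd$arrival_time, charge, mass)
  colsum <- colSums(atd$intensity)
  empty <- colsum <= 0
  norm <- atd$intensity
  norm[, !empty] <- sweep(atd$intensity[, !empty, drop = FALSE], 2,
                          colsum[!empty], "/")
  structure(list(energy_axis = charge * atd$voltage, ccs_axis = ccs,
                 intensity = norm, charge = as.integer(charge),
                 empty_columns = which(empty)),
            class = "ciu_fingerprint")
}

#' @export
print.ciu_fingerprint <- function(x, ...) {
  cat(sprintf("ciu_fingerprint: %d energies (%.0f-%.0f eV), CCS %.0f-%.0f A^2, charge %d+\n",
              length(x$energy_axis), min(x$energy_axis), max(x$energy_axis),
              min(x$ccs_axis), max(x$ccs_axis), x$charge))
  invisible(x)
}

# Intensity-weighted mean CCS of one normalized column.
column_mean_ccs <- function(ccs, w) if (sum(w) <= 0) NA_real_ else sum(ccs * w) / sum(w)

#' Quantify unfolding from a CIU fingerprint
#'
#' The compact and unfolded CCS are taken as the intensity-weighted mean CCS
#' of the lowest- and highest-energy columns.  Each column is decomposed into
#' compact/unfolded weights by splitting at the CCS midway between the two
#' centroids.  Onset is the first energy where the compact weight drops below
#' `compact_threshold`; the midpoint is the first energy where it drops below
#' 0.5.  Classification: `two_state` if the occupancy of the intermediate CCS
#' band (central half of the compact-unfolded gap) never exceeds
#' `intermediate_max`, else `gradual`.
#'
#' @param fp a `ciu_fingerprint`.
#' @param compact_threshold compact-weight threshold defining the onset.
#' @param intermediate_max maximum tolerated intermediate-band occupancy for a
#'   two-state call.
#' @return an `unfolding_result` with `compact_ccs`, `unfolded_ccs`,
#'   `percent_expansion`, `onset_energy`, `midpoint_energy`, `n_states`,
#'   `classification`, `censored` and the per-column `compact_weight`.
#' @export
unfolding_metrics <- function(fp, compact_threshold = 0.9,
                              intermediate_max = 0.10) {
  stopifnot(inherits(fp, "ciu_fingerprint"))
  E <- fp$energy_axis; ccs <- fp$ccs_axis; M <- fp$intensity
  use <- setdiff(seq_along(E), fp$empty_columns)
  if (length(use) < 2L) stop("need at least 2 non-empty energy columns")
  compact_ccs <- column_mean_ccs(ccs, M[, use[1]])
  unfolded_ccs <- column_mean_ccs(ccs, M[, use[length(use)]])
  if (unfolded_ccs < compact_ccs) unfolded_ccs <- compact_ccs
  # no resolvable transition in range: first- and last-column centroids
  # coincide (< 2% apart, well below any meaningful unfolding expansion)
  if ((unfolded_ccs - compact_ccs) / compact_ccs < 0.02) {
    return(structure(list(
      compact_ccs = compact_ccs, unfolded_ccs = unfolded_ccs,
      percent_expansion = 100 * (unfolded_ccs - compact_ccs) / compact_ccs,
      onset_energy = NA_real_, midpoint_energy = NA_real_,
      censored = TRUE, max_energy = max(E),
      n_states = count_persistent_modes(ccs, M[, use, drop = FALSE]),
      classification = "two_state", intermediate_occupancy = 0,
      compact_weight = rep(1, length(E)), energy_axis = E),
      class = "unfolding_result"))
  }
  split_ccs <- (compact_ccs + unfolded_ccs) / 2
  w_compact <- colSums(M[ccs <= split_ccs, , drop = FALSE])
  w_compact[fp$empty_columns] <- NA_real_

  gap <- unfolded_ccs - compact_ccs
  band <- ccs > compact_ccs + 0.25 * gap & ccs < unfolded_ccs - 0.25 * gap
  inter_occ <- if (gap > 0 && any(band))
    max(colSums(M[band, use, drop = FALSE])) else 0

  below <- function(thr) {
    # inclusive, with a float guard: the energy where the compact weight has
    # dropped to (or below) the threshold
    i <- which(w_compact <= thr + 1e-9 & !is.na(w_compact))
    if (length(i)) E[i[1]] else NA_real_
  }
  onset <- below(compact_threshold)
  midpoint <- below(0.5)
  censored <- is.na(midpoint)
  if (!is.na(onset) && !is.na(midpoint) && onset > midpoint) onset <- midpoint

  n_states <- count_persistent_modes(ccs, M[, use, drop = FALSE])
  expansion <- 100 * (unfolded_ccs - compact_ccs) / compact_ccs
  classification <- if (gap > 0 && inter_occ > intermediate_max) "gradual" else "two_state"
  structure(list(compact_ccs = compact_ccs, unfolded_ccs = unfolded_ccs,
                 percent_expansion = expansion,
                 onset_energy = onset, midpoint_energy = midpoint,
                 censored = censored, max_energy = max(E),
                 n_states = n_states, classification = classification,
                 intermediate_occupancy = inter_occ,
                 compact_weight = w_compact, energy_axis = E),
            class = "unfolding_result")
}

# Cluster per-column mode positions; a state is a mode position recurring in
# at least `min_columns` columns within `tol_frac` of the CCS range.
count_persistent_modes <- function(ccs, M, rel_height = 0.2, tol_frac = 0.05,
                                   min_columns = 2L) {
  pos <- unlist(lapply(seq_len(ncol(M)), function(j) {
    y <- M[, j]
    if (max(y) <= 0) return(numeric(0))
    n <- length(y)
    i <- which(y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf) & y >= rel_height * max(y))
    ccs[i]
  }))
  if (!length(pos)) return(0L)
  tol <- tol_frac * diff(range(ccs))
  pos <- sort(pos)
  cl <- cumsum(c(TRUE, diff(pos) > tol))
  sum(tabulate(cl) >= min_columns)
}

#' @export
print.unfolding_result <- function(x, ...) {
  cat(sprintf(paste0("unfolding_result: compact %.0f A^2, unfolded %.0f A^2 ",
                     "(+%.1f%%), onset %s eV, midpoint %s eV, %s (%d states)\n"),
              x$compact_ccs, x$unfolded_ccs, x$percent_expansion,
              if (is.na(x$onset_energy)) sprintf("> %g", x$max_energy) else
                format(x$onset_energy),
              if (is.na(x$midpoint_energy)) sprintf("> %g", x$max_energy) else
                format(x$midpoint_energy),
              x$classification, x$n_states))
  invisible(x)
}

#' Stabilization shift between two unfolding results
#'
#' Signed differences `b - a`; a positive onset shift means `b` is stabilized
#' relative to `a`.  Censored inputs (no transition in range) propagate as
#' intervals: a censored `b` yields `delta_onset = c(Emax_b - onset_a, Inf)`.
#'
#' @param a,b `unfolding_result` objects from the same charge state.
#' @return list with `delta_onset` (scalar, or length-2 interval when
#'   censored), `delta_percent_expansion`, and `censored`.
#' @export
stabilization_shift <- function(a, b) {
  stopifnot(inherits(a, "unfolding_result"), inherits(b, "unfolding_result"))
  onset_a <- if (is.na(a$onset_energy)) c(a$max_energy, Inf) else a$onset_energy
  onset_b <- if (is.na(b$onset_energy)) c(b$max_energy, Inf) else b$onset_energy
  censored <- length(onset_a) > 1L || length(onset_b) > 1L
  delta <- if (!censored) onset_b - onset_a
    else if (length(onset_b) > 1L && length(onset_a) == 1L)
      c(onset_b[1] - onset_a, Inf)
    else if (length(onset_a) > 1L && length(onset_b) == 1L)
      c(-Inf, onset_b - onset_a[1])
    else c(-Inf, Inf)
  list(delta_onset = delta,
       delta_percent_expansion = b$percent_expansion - a$percent_expansion,
       censored = censored)
}
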