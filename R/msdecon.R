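# Charge-state envelope deconvolution and lipid-binding quantification for
# native mass spectra of membrane-protein complexes.
#
# A spectrum is profile-mode (m/z, intensity) with per-spectrum metadata
# (collision voltage, lipid concentration, label).  Peaks are modelled as
# Gaussian in m/z; centroids are refined by local quadratic interpolation.
# Theoretical m/z for an oligomer with adducts in positive-ion mode:
#   m/z = (k * M_protomer + n * M_adduct + z * m_H+) / z,  m_H+ = 1.00728 Da.

#' Construct a mass spectrum
#'
#' @param mz strictly increasing m/z values (Th).
#' @param intensity non-negative intensities, same length.
#' @param collision_voltage trap collision voltage (V), optional.
#' @param lipid_concentration added lipid concentration (uM), optional.
#' @param label free-text label.
#' @return a `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, collision_voltage = NA_real_,
                          lipid_concentration = NA_real_, label = "") {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) && any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = mz, intensity = intensity,
                 metadata = list(collision_voltage = as.numeric(collision_voltage),
                                 lipid_concentration = as.numeric(lipid_concentration),
                                 label = label)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("mass_spectrum: %d points, m/z %.1f-%.1f%s\n", length(x$mz),
              min(x$mz), max(x$mz),
              if (is.finite(x$metadata$collision_voltage))
                sprintf(", CV %g V", x$metadata$collision_voltage) else ""))
  invisible(x)
}

#' Describe a candidate species for deconvolution
#'
#' @param base_mass protomer mass (Da).
#' @param oligomer_state number of protomers (>= 1).
#' @param adduct_mass mass of one adduct (Da); 0 disables adducts.
#' @param max_adducts maximum adduct count considered.
#' @param charge_range integer range of charge states, length 2.
#' @param label species label.
#' @export
species_model <- function(base_mass, oligomer_state = 1L, adduct_mass = 0,
                          max_adducts = 0L, charge_range = c(8L, 20L),
                          label = NULL) {
  stopifnot(base_mass > 0, oligomer_state >= 1L, max_adducts >= 0L,
            length(charge_range) == 2L, charge_range[1] >= 1L,
            charge_range[1] <= charge_range[2])
  if (is.null(label))
    label <- sprintf("%dmer_%.0fDa", oligomer_state, base_mass)
  structure(list(base_mass = base_mass,
                 oligomer_state = as.integer(oligomer_state),
                 adduct_mass = adduct_mass,
                 max_adducts = as.integer(max_adducts),
                 charge_range = as.integer(charge_range),
                 label = label),
            class = "species_model")
}

theoretical_mz <- function(species, charge, n_adducts = 0L) {
  (species$oligomer_state * species$base_mass +
     n_adducts * species$adduct_mass + charge * PROTON_MASS) / charge
}

#' Pick peaks from a profile spectrum
#'
#' Local maxima above `snr_min` times the noise floor (median absolute
#' intensity), with centroid refined by fitting a parabola through the apex
#' and its two neighbours.
#'
#' @param spectrum a `mass_spectrum`.
#' @param snr_min minimum apex-to-noise ratio.
#' @return data frame with `mz`, `intensity`.
#' @export
pick_peaks <- function(spectrum, snr_min = 3) {
  y <- spectrum$intensity; x <- spectrum$mz
  n <- length(y)
  if (n < 3L) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  noise <- median(y[y > 0])
  if (!is.finite(noise) || noise <= 0) noise <- max(y) * 1e-6
  apex <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  apex <- apex[y[apex] >= snr_min * noise]
  if (!length(apex)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  # quadratic interpolation of the apex position
  cmz <- vapply(apex, function(i) {
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- (y1 - 2 * y2 + y3)
    if (denom >= 0) return(x[i])
    delta <- 0.5 * (y1 - y3) / denom
    delta <- max(min(delta, 0.5), -0.5)
    x[i] + delta * (x[min(i + 1L, n)] - x[max(i - 1L, 1L)]) / 2
  }, numeric(1))
  data.frame(mz = cmz, intensity = y[apex])
}

#' Deconvolve a spectrum against candidate species
#'
#' Matches picked peaks to the nearest theoretical m/z of any
#' (species, charge, n_adducts) combination within a ppm tolerance.
#'
#' @param spectrum a `mass_spectrum`.
#' @param candidates list of [species_model()] objects.
#' @param tolerance_ppm matching tolerance (ppm).
#' @param snr_min peak-picking threshold, see [pick_peaks()].
#' @return a `deconvolution` with `assignments` (one row per matched peak:
#'   species label, oligomer_state, charge, n_adducts, theoretical_mz,
#'   matched_mz, matched_intensity, ppm_error), `abundance` (summed matched
#'   intensity per species), `neutral_mass` (intensity-weighted adduct-free
#'   mass estimate per species), and `unmatched` peaks.
#' @export
deconvolve <- function(spectrum, candidates, tolerance_ppm = 200, snr_min = 3) {
  if (!length(candidates)) stop("need at least one candidate species")
  if (inherits(candidates, "species_model")) candidates <- list(candidates)
  stopifnot(tolerance_ppm > 0)
  if (!length(spectrum$mz)) stop("empty spectrum")
  peaks <- pick_peaks(spectrum, snr_min = snr_min)
  if (!nrow(peaks)) {
    warning("no peak above the noise floor; returning empty assignment")
    return(structure(list(assignments = empty_assignments(), abundance = numeric(0),
                          neutral_mass = numeric(0), unmatched = peaks),
                     class = "deconvolution"))
  }
  theo <- do.call(rbind, lapply(candidates, function(sp) {
    grid <- expand.grid(charge = seq(sp$charge_range[1], sp$charge_range[2]),
                        n_adducts = 0:sp$max_adducts)
    data.frame(label = sp$label, oligomer_state = sp$oligomer_state,
               charge = grid$charge, n_adducts = grid$n_adducts,
               theoretical_mz = theoretical_mz(sp, grid$charge, grid$n_adducts),
               base_mass = sp$base_mass, adduct_mass = sp$adduct_mass)
  }))
  idx <- vapply(peaks$mz, function(m) which.min(abs(theo$theoretical_mz - m)),
                integer(1))
  ppm <- (peaks$mz - theo$theoretical_mz[idx]) / theo$theoretical_mz[idx] * 1e6
  ok <- abs(ppm) <= tolerance_ppm
  assignments <- data.frame(
    label = theo$label[idx][ok], oligomer_state = theo$oligomer_state[idx][ok],
    charge = theo$charge[idx][ok], n_adducts = theo$n_adducts[idx][ok],
    theoretical_mz = theo$theoretical_mz[idx][ok], matched_mz = peaks$mz[ok],
    matched_intensity = peaks$intensity[ok], ppm_error = ppm[ok])
  # one peak per theoretical position: keep the most intense claimant
  if (nrow(assignments)) {
    key <- paste(assignments$label, assignments$charge, assignments$n_adducts)
    keep <- unlist(lapply(split(seq_len(nrow(assignments)), key), function(i)
      i[which.max(assignments$matched_intensity[i])]))
    assignments <- assignments[sort(keep), , drop = FALSE]
    rownames(assignments) <- NULL
  }
  abundance <- vapply(split(assignments$matched_intensity, assignments$label),
                      sum, numeric(1))
  neutral <- vapply(split(seq_len(nrow(assignments)), assignments$label),
                    function(i) {
    a <- assignments[i, ]
    m <- a$matched_mz * a$charge - a$charge * PROTON_MASS -
      a$n_adducts * vapply(a$label, function(l)
        theo$adduct_mass[match(l, theo$label)], numeric(1))
    weighted.mean(m, a$matched_intensity)
  }, numeric(1))
  structure(list(assignments = assignments, abundance = abundance,
                 neutral_mass = neutral, unmatched = peaks[!ok, , drop = FALSE]),
            class = "deconvolution")
}

empty_assignments <- function() {
  data.frame(label = character(0), oligomer_state = integer(0),
             charge = integer(0), n_adducts = integer(0),
             theoretical_mz = numeric(0), matched_mz = numeric(0),
             matched_intensity = numeric(0), ppm_error = numeric(0))
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("deconvolution: %d assigned peaks, %d species, %d unmatched\n",
              nrow(x$assignments), length(x$abundance), nrow(x$unmatched)))
  for (l in names(x$abundance))
    cat(sprintf("  %s: abundance %.3g, neutral mass %.1f Da\n",
                l, x$abundance[[l]], x$neutral_mass[[l]]))
  invisible(x)
}

#' Lipid-adduct occupancy profile of a deconvolved spectrum
#'
#' Intensity-weighted histogram over the number of bound adducts, with mean
#' occupancy sum(n * w(n)).
#'
#' @param assignments the `assignments` data frame of a [deconvolve()] result
#'   (or a `deconvolution`).
#' @param species_label restrict to one species label (default: all).
#' @return list with `distribution` (data frame n_adducts, weight) and `mean`.
#' @export
adduct_profile <- function(assignments, species_label = NULL) {
  if (inherits(assignments, "deconvolution")) assignments <- assignments$assignments
  if (!is.null(species_label))
    assignments <- assignments[assignments$label == species_label, , drop = FALSE]
  if (!nrow(assignments)) stop("no assignments to profile")
  w <- vapply(split(assignments$matched_intensity, assignments$n_adducts),
              sum, numeric(1))
  n <- as.integer(names(w))
  w <- w / sum(w)
  list(distribution = data.frame(n_adducts = n, weight = unname(w)),
       mean = sum(n * w))
}

#' Classify a lipid titration as saturating or non-saturating
#'
#' Fits a single-site saturation model `occ = Bmax * c / (Kd + c)` and a
#' linear non-specific model `occ = a * c + b`, compares them by small-sample
#' corrected AIC, and requires a margin of `delta_aic_min` before calling the
#' binding saturating (specific).
#'
#' @param concentration lipid concentrations (uM), >= 4 values.
#' @param occupancy mean adduct occupancy at each concentration.
#' @param delta_aic_min AICc margin required to prefer saturation.
#' @return a `binding_curve` with `classification` (`"saturating"` or
#'   `"non_saturating"`), fitted `parameters`, and per-model AICc.
#' @export
titration_analysis <- function(concentration, occupancy, delta_aic_min = 2) {
  x <- as.numeric(concentration); y <- as.numeric(occupancy)
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 concentrations")
  if (diff(range(x)) == 0) stop("degenerate titration: all concentrations equal")
  n <- length(x)
  aicc <- function(rss, k) n * log(rss / n + 1e-300) + 2 * k +
    2 * k * (k + 1) / max(n - k - 1, 1e-9)

  lin <- lm(y ~ x)
  rss_lin <- sum(residuals(lin)^2)
  fit_lin <- list(slope = unname(coef(lin)[2]), intercept = unname(coef(lin)[1]))

  sat <- tryCatch({
    start <- list(Bmax = max(y) * 1.5 + 1e-6, Kd = median(x))
    # warnOnly + suppressWarnings: a non-converged saturation fit simply
    # loses the AICc comparison below
    suppressWarnings(nls(y ~ Bmax * x / (Kd + x), start = start,
                         lower = c(Bmax = 0, Kd = 1e-9), algorithm = "port",
                         control = list(warnOnly = TRUE)))
  }, error = function(e) NULL)
  rss_sat <- if (is.null(sat)) Inf else sum(residuals(sat)^2)

  aic_lin <- aicc(rss_lin, 3)  # slope, intercept, sigma
  aic_sat <- if (is.null(sat)) Inf else aicc(rss_sat, 3)  # Bmax, Kd, sigma
  saturating <- is.finite(aic_sat) && (aic_lin - aic_sat) >= delta_aic_min
  params <- if (saturating) as.list(coef(sat)) else fit_lin
  structure(list(x = x, y = y,
                 classification = if (saturating) "saturating" else "non_saturating",
                 parameters = params,
                 aicc = c(linear = aic_lin, saturating = aic_sat)),
            class = "binding_curve")
}

#' Gas-phase dissociation curve of a lipid-protein complex
#'
#' Computes the bound fraction (one-adduct vs adduct-free species intensity)
#' at each collision voltage, fits a descending logistic, and reports the
#' midpoint voltage CV50.  Complexes that never dissociate in range yield a
#' censored CV50 reported as the interval `(max voltage, Inf)`.
#'
#' @param spectra list of `mass_spectrum` at increasing collision voltage
#'   (read from each spectrum's metadata).
#' @param species a [species_model()] with `max_adducts >= 1`.
#' @param tolerance_ppm,snr_min passed to [deconvolve()].
#' @return a `binding_curve` with `cv50` (V), `censored` flag,
#'   `non_monotonic` flag, and the fitted logistic parameters.
#' @export
dissociation_curve <- function(spectra, species, tolerance_ppm = 200, snr_min = 3) {
  if (length(spectra) < 4L) stop("need spectra at >= 4 collision voltages")
  if (species$max_adducts < 1L) stop("species must allow at least one adduct")
  v <- vapply(spectra, function(s) s$metadata$collision_voltage, numeric(1))
  if (any(!is.finite(v))) stop("every spectrum needs a collision_voltage")
  ord <- order(v); v <- v[ord]; spectra <- spectra[ord]
  frac <- vapply(spectra, function(s) {
    d <- deconvolve(s, list(species), tolerance_ppm = tolerance_ppm,
                    snr_min = snr_min)
    a <- d$assignments
    bound <- sum(a$matched_intensity[a$n_adducts >= 1L])
    total <- sum(a$matched_intensity)
    if (total <= 0) NA_real_ else bound / total
  }, numeric(1))
  fit_dissociation(v, frac)
}

#' Fit a descending logistic to bound fractions
#'
#' Workhorse behind [dissociation_curve()]; usable directly on precomputed
#' bound fractions.
#'
#' @param voltage collision voltages (V).
#' @param bound_fraction bound fractions in `[0, 1]`.
#' @return a `binding_curve`, see [dissociation_curve()].
#' @export
fit_dissociation <- function(voltage, bound_fraction) {
  keep <- is.finite(bound_fraction)
  v <- voltage[keep]; f <- pmin(pmax(bound_fraction[keep], 0), 1)
  if (length(v) < 4L) stop("need >= 4 usable voltages")
  rises <- diff(f)
  non_monotonic <- any(rises > 0.1)  # beyond noise tolerance
  if (non_monotonic)
    warning("bound fraction is non-monotonic beyond noise tolerance; fit returned anyway")
  censored <- all(f > 0.5)
  obj <- function(p) sum((f - 1 / (1 + exp((v - p[1]) / max(p[2], 1e-6))))^2)
  init <- c(cv50 = if (any(f <= 0.5)) v[which(f <= 0.5)[1]] else max(v),
            width = diff(range(v)) / 8)
  opt <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  cv50 <- unname(opt$par[1])
  if (censored) cv50 <- c(max(v), Inf)
  structure(list(x = v, y = f,
                 cv50 = cv50, censored = censored,
                 non_monotonic = non_monotonic,
                 parameters = list(cv50 = unname(opt$par[1]),
                                   width = abs(unname(opt$par[2]))),
                 rss = opt$value),
            class = "binding_curve")
}

#' Rank lipid gas-phase stabilities by CV50
#'
#' @param curves named list of `binding_curve` objects from
#'   [dissociation_curve()].
#' @return data frame sorted by descending CV50 (censored curves first).
#' @export
stability_ranking <- function(curves) {
  stopifnot(length(curves) >= 1L, !is.null(names(curves)))
  cv <- vapply(curves, function(cu) {
    if (isTRUE(cu$censored)) Inf else cu$cv50[1]
  }, numeric(1))
  out <- data.frame(lipid = names(curves), cv50 = unname(cv))
  out[order(-out$cv50), , drop = FALSE]
}
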