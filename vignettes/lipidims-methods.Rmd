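---
title: "Methods: lipid interactions of membrane proteins by native IM-MS and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid interactions of membrane proteins by native IM-MS and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidims)
```

# Scope

`lipidims` implements the computational side of a combined native ion-mobility
mass spectrometry (IM-MS) / molecular-dynamics study of membrane-protein-lipid
interactions, of the kind used to dissect lipid binding and conformational
stability of Na⁺/H⁺ antiporters. It covers five analysis stages — lipid adduct
mass arithmetic, charge-state envelope deconvolution with binding
quantification, traveling-wave CCS calibration with collision-induced
unfolding (CIU) quantification, structure-based CCS estimation, and
membrane-trajectory geometry — plus seeded synthetic-data generators with
planted ground truth, so every stage is testable without instrument data or
cluster-scale simulations.

# Lipid mass model

Species are described by a lipid class (PE, PG, CDL, MAG) and a *total* acyl
composition `n:d` (carbons : double bonds summed over all chains); the
distribution over individual chains is not modelled because adduct masses only
constrain the totals. Formulas are closed forms over the class head-group
skeleton, e.g. diacyl-PE `n:d` is C(n+5) H(2n−2d+10) N O8 P. Each two-carbon
saturated increment adds 28.05 Da; each double bond removes 2.016 Da.

**Reporting form.** PE, PG and MAG are reported as neutral (free-acid)
species. Cardiolipin is a diacid whose first phosphate proton is essentially
always dissociated; the lipidomics tables that adduct masses are compared
against quote the singly deprotonated species. We verified arithmetically that
only this convention reproduces the canonical average masses (CDL 66:2 =
1376.9 Da, CDL 70:3 = 1431.0 Da; the neutral free acid is 1.0 Da higher) *and*
makes a 1430-Da adduct assign to CDL 70:3 rather than 70:4. CDL therefore
defaults to the monoanion; both forms are available via the `form` argument of
`build_species()`.

**Assignment grid.** `assign_adduct()` searches even-carbon compositions by
default (`carbon_step = 2`, the biosynthetic convention). This is not merely
cosmetic: on an all-integer carbon grid, one extra CH₂ (+14.027 Da) is within
0.09 Da of seven extra double bonds (−14.112 Da), so odd/even-mixed candidate
sets contain near-degenerate pairs and sub-0.1-Da assignment would be
meaningless. On the even grid the closest distinct candidates are ~2 Da apart,
and a ±0.4 Da perturbation always recovers the planted composition. Ties are
broken toward fewer double bonds, then fewer carbons.

# Spectrum model and deconvolution

Spectra are profile-mode (m/z, intensity) with per-spectrum metadata
(collision voltage, lipid concentration). Peaks are Gaussian in m/z; apexes
are centroided by local quadratic interpolation. Positive-ion mode is assumed
throughout, with theoretical positions
`(k·M + n·M_adduct + z·1.00728)/z` for a `k`-mer with `n` adducts at charge
`z`. Peaks are matched to the nearest theoretical position within a ppm
tolerance (default 200 ppm, appropriate for broad native-MS peaks of membrane
proteins); per-species abundance is the summed matched intensity, and the
neutral mass is the intensity-weighted mean over matched charge states.

**Titration classification.** Mean adduct occupancy versus lipid
concentration is fit with (i) a single-site saturation model
`B_max·c/(K_d+c)` and (ii) a straight line (non-specific binding). Models are
compared by small-sample-corrected AIC and saturation must win by ΔAICc ≥ 2;
this deliberately biases against over-calling specific binding on noisy
titrations, mirroring how non-specific annular binding is diagnosed in
practice (concentration-dependent adduct growth with no saturation).

**Dissociation curves.** The bound fraction (one-adduct over total species
intensity) versus collision voltage is fit with a descending logistic; the
midpoint CV50 ranks gas-phase stabilities (e.g. anionic PG > zwitterionic
PE > uncharged MAG). A complex that never dissociates in range is *censored*
and reported as the interval `(V_max, Inf)`, never as a point estimate.

# CCS calibration and CIU quantification

The traveling-wave calibration follows the standard chain: dead-time
correction `t' = t_A − edc·√(m/z)/1000` (default `edc = 1.41`), charge and
reduced-mass correction `Ω' = Ω·√µ/z` with N₂ (28.0134 Da) as drift gas, and
a log-log linear fit `Ω' = A·t'^B`. On noise-free power-law data the fit
round-trips exactly; predictions are strictly monotone in arrival time.

CIU fingerprints are intensity over (lab-frame energy × CCS), with lab-frame
energy = charge × trap collision voltage — consistent with a 700–1500 eV
activation range at 11+ corresponding to 64–136 V inside a 20–200 V
instrument range. Each energy column is normalized to unit sum (all-zero
columns are flagged, never silently normalized).

**Unfolding metrics.** The compact and unfolded CCS are the intensity-weighted
centroids of the lowest- and highest-energy columns; columns are decomposed
into compact/unfolded weights by a hard split at the midpoint CCS. The onset
is the first energy at which the compact weight drops to the threshold
(default 0.9), the midpoint where it reaches 0.5; both are read on the energy
grid, so recovery is quoted to within one energy step.
`percent_expansion = 100·(unfolded − compact)/compact`. Classification is
`two_state` when the occupancy of the intermediate CCS band (central half of
the compact–unfolded gap) never exceeds 10% — "only a very minor population
of intermediates" — and `gradual` otherwise (a drifting unimodal continuum
crosses the band and fails the bound). If the first- and last-column
centroids differ by < 2% the surface is treated as having no transition in
range: onset and midpoint are censored rather than reported as the first grid
energy. The published percent expansions for the antiporter system (21%,
~12%, ~16%) are not asserted as targets: their printed arithmetic is not
self-consistent under any single reference choice, so the package documents
its formula and validates on synthetic surfaces instead.

# Projection-approximation CCS

`pa_ccs()` estimates the orientation-averaged projected area of a hard-sphere
atom model: uniformly random orientations (quaternion sampling from R's seeded
RNG), hit/miss probe sampling against disks of radius (vdW + probe) with a
2-D cell list, and a multiplicative scale factor. Defaults: probe radius
1.0 Å (the He-equivalent convention of the standard CCS tools) and scale
factor 1.14, emulating the trajectory-method calibration of
projection-approximation values. The cited tool's exact parameters are not
published, so these are documented defaults, not asserted equivalents; the
crystal-structure comparison is treated as a consistency check with a 5%
band, and is left red in this build because the reference coordinates cannot
be fetched offline. The engine itself is validated against an analytic sphere
(π(r+r_probe)²), a deterministic two-disk overlap-area oracle, rigid-motion
invariance, monotonicity under atom addition, and 1/√N error scaling.
`trajectory_ccs()` averages per-frame estimates over a trailing window
(default the last half, matching the usual reporting convention), and
`ccs_with_without_ligands()` runs the same seed stream with and without the
lipid selection.

# Membrane-trajectory geometry

Frames are rigidly superposed onto frame 1 by a Kabsch fit of the protein
selection (alignment is idempotent and leaves inter-atomic distances
unchanged). Contacts use the inclusive criterion min-distance ≤ 2.15 Å
between lipid head-group atoms and protein atoms (heavy atoms; hydrogen
handling in the criterion is unspecified upstream, so head-group selections
are configurable); the cell-list kernel is exact, and tests assert equality
with an O(N·M) brute-force scan. Heavy clashes (any lipid atom within 0.5 Å
of the protein) remove the whole lipid. Leaflets are assigned from the
head-group phosphorus along z; the midplane is initialized at the median
phosphorus z and refined to the midpoint of the two leaflet centroids — the
pure median is biased whenever leaflet populations differ, which is exactly
the situation of interest (e.g. a 10/13 annular split). The annular shell is
the set of lipids with contact occupancy ≥ 0.9 ("full contact" is
qualitative upstream; the threshold is exposed).

Phosphate densities are product-Gaussian KDEs of the phosphorus positions of
in-contact lipids over all frames, with Scott's-rule bandwidth per axis
(`σ_i·n^(−1/7)`) by default and count-density normalization: the grid
integral equals the number of contributing points to within 1%. Values are
converted to nm⁻³ (1 nm⁻³ = 10⁻³ Å⁻³) so the conventional rendering cutoff
2×10⁻⁵ nm⁻³ applies directly; grids export to OpenDX text. Thickness maps
bin phosphorus positions into xy cells (upper mean z minus lower mean z,
averaged over frames); uncovered cells are masked `NA`, never zero-filled.
Hydrogen bonds use the common geometric criterion: donor–acceptor ≤ 3.5 Å
and donor–hydrogen–acceptor angle ≥ 150°, with donors identified as N/O
bearing a covalent hydrogen (≤ 1.25 Å, same molecule).

# Synthetic worlds and what a green test establishes

Generator defaults state the emulated world once: an 82,450-Da dimer with
charge states 10–13 for spectra; two-state surfaces between ~5,000 and
~6,000 Å² with onsets/midpoints in the 900–2,400 eV range for CIU; a
120 × 95 Å PE-like bilayer (≈380 lipids at ~60 Å² per lipid, leaflet
phosphates at ±19 Å) around a rigid cylindrical point-model protein, with a
planted annular shell of 23 lipids split 10/13 across leaflets and three
ideal hydrogen bonds per shell lipid. Noise models: uniform baseline at
`peak/SNR` for spectra; counting-statistics noise (sd ∝ √signal, peak sd =
peak/SNR) plus a weak baseline for ATDs. Planted contact and H-bond atoms are
exempt from thermal jitter so that "planted" quantities are exact; when a
thickness depression is planted, one lipid per leaflet samples its center so
the minimum is observable at any lipid density.

These worlds are geometric, not physical: there is no force field, no lipid
diffusion, no detergent, and the toy protein is rigid. A green test therefore
establishes that each analysis stage recovers what was planted at the stated
tolerance — not that the pipeline reproduces instrument physics. The
instrument-scale published values (experimental CCS of 4,550–5,730 Å²,
onset energies 900/2,000/>2,300 eV, the ~20% high-temperature CCS jump) are
demonstrated as *logic* on synthetic scenarios, not as numeric targets.

# Numerical choices

* Proton mass 1.00728 Da; N₂ 28.0134 Da; embedded IUPAC atomic weights.
* Contact cutoffs are inclusive (`d ≤ cutoff` on squared distances, so a
  lipid placed exactly at 2.15 Å is a contact).
* Onset/midpoint threshold crossings are inclusive with a 10⁻⁹ float guard.
* KDE kernels are truncated at 4 bandwidths (mass loss < 10⁻⁴ per axis,
  inside the 1% conservation budget).
* A lipid exactly at the midplane ties toward the upper leaflet when
  equidistant from both centroids.
* Censoring is propagated through stabilization shifts as interval
  arithmetic (`> E_max − onset_a`), never collapsed to a number.
* Seeds fan out from a root seed as `(1009·seed + 97·offset) mod (2³¹−1)`,
  keeping generator substreams independent and 32-bit safe.

# Known limitations

* The PDB reader is minimal (fixed-width ATOM/HETATM, orthorhombic CRYST1);
  it is not a general PDB parser.
* Periodic handling is minimum-image/wrapping for orthorhombic boxes only.
* The mixture decomposition in CIU uses a hard split, which is robust for
  well-separated states but underestimates weights when state separation
  approaches the peak width.
* No isotopic fine structure, no MS/MS fragment prediction, no instrument
  wave-dynamics model, and no force-field energetics anywhere.
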