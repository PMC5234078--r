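# lipidims

Analysis pipeline linking **native ion-mobility mass spectrometry (IM-MS)**
of membrane-protein-lipid complexes with **MD-trajectory lipid analysis**,
for studies of how annular lipids stabilize membrane transporters (e.g.
Na⁺/H⁺ antiporter dimers). It is aimed at structural mass spectrometrists and
simulators who need a tested, scriptable implementation of:

* **Lipid adduct arithmetic** — build PE/PG/CDL/MAG species from a total acyl
  composition `n:d`, with average/monoisotopic masses from embedded atomic
  weights, and assign observed adduct masses to compositions
  (`m/z` ladders spaced 28.05 Da per two acyl carbons).
* **Charge-state deconvolution** — match profile-mode peaks to
  `(k·M + n·M_adduct + z·m_H)/z`, recover oligomeric state, neutral mass and
  adduct occupancy; classify titrations (saturating vs non-specific,
  ΔAICc ≥ 2) and rank lipid gas-phase stabilities by dissociation CV50.
* **TWIMS CCS calibration + CIU** — power-law calibration
  `Ω' = A·t'^B` on dead-time- and reduced-mass-corrected variables;
  collision-induced unfolding fingerprints over (charge × voltage) lab-frame
  energy with per-column normalization; onset/midpoint energies, percent
  expansion `100·(Ω_unf − Ω_cpt)/Ω_cpt`, two-state vs gradual classification.
* **Structure CCS** — Monte-Carlo projection approximation with a
  trajectory-method scale factor (defaults: probe 1.0 Å, scale 1.14), on PDB
  structures or trajectory frames (trailing-window averages, with/without
  bound lipids).
* **Membrane geometry** — frame alignment, inclusive 2.15 Å contact
  detection (cell-list, oracle-exact), 0.5 Å clash removal, leaflet
  assignment, annular-shell selection by occupancy, 3-D Gaussian phosphate
  density (count-normalized, nm⁻³, OpenDX export, 2×10⁻⁵ nm⁻³ cutoff
  thresholding), bilayer thickness maps, and H-bond statistics
  (≤ 3.5 Å, ≥ 150°).
* **Synthetic generators** — every input above with planted ground truth
  (seeded, bit-reproducible), so the full pipeline is testable offline.

## Worked example

```r
library(lipidims)

# A co-purified lipid of mass 1,430 Da with a 28-Da ladder: cardiolipin?
assign_adduct(1430, "CDL", c(60L, 80L), c(0L, 8L))$best_species
#> CDL 70:3 (monoanion) C79H147O17P2  avg 1430.98 Da  mono 1430.01 Da
build_species("CDL", 66, 2)$average_mass   # most common E. coli CDL
#> [1] 1376.884

# Synthetic CIU: lipid-free vs lipid-bound unfolding
g  <- gen_ciu(5000, 6000, onset = 900,  midpoint = 1100, seed = 1, snr = Inf)
fp <- build_fingerprint(g$atd, g$cal, charge = 11, mass = 82450)
unfolding_metrics(fp)
#> unfolding_result: compact 5000 A^2, unfolded 6000 A^2 (+20.0%),
#>   onset 1000 eV, midpoint 1200 eV, two_state (2 states)
# (onset/midpoint are read on the 100-eV energy grid: one step above the
#  planted 900/1100, the documented grid resolution)

# Planted membrane: recover the annular shell and its leaflet split
r <- run_traj_workflow(list(seed = 3))
r$shell_size; unlist(r$shell_per_leaflet); r$hbond_mean_per_lipid
#> [1] 23
#> lower upper
#>    10    13
#> [1] 3
```

The printed numbers above are produced by the code as shown: the 1,430-Da
adduct assigns to cardiolipin 70:3, the planted unfolding surface returns
its onset/midpoint to within one energy step with a 20% expansion, and the planted
23-lipid annular shell is recovered with its 10/13 leaflet split and three
ideal hydrogen bonds per lipid.

## Command line

```sh
inst/cli/lipidims lipid-mass CDL 70:3
inst/cli/lipidims ccs compute structure.pdb --probe 1.0 --scale 1.14 --seed 1
inst/cli/lipidims synth ciu --out demo --seed 1
inst/cli/lipidims run traj --out report.json
```

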