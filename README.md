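# roacollagen

Simulation and analysis of Raman and Raman optical activity (ROA) spectra
of collagen-type triple-helical peptides, in R.

Collagen adopts a triple helix of three polyproline-II (PPII) strands with
glycine in every third position; proline and 4R-hydroxyproline (Hyp)
stabilize the fold. ROA — the difference in Raman scattering of right- vs
left-circularly polarized light — is exquisitely sensitive to this chiral
architecture: the amide-I region shows a characteristic (−/+) couplet, and
a positive ROA band near 473 cm⁻¹ (a Hyp ring deformation) distinguishes
collagen type I from type II. Because the effect is tiny (circular
intensity differences, CID = (I_R − I_L)/(I_R + I_L), near 10⁻³), both the
simulation and the analysis of such spectra need careful numerics.

`roacollagen` implements the full desk-scale computational protocol around
these measurements:

- **Peptide models** — triplet notation (`"(PHG)9PHA"`, `"D-(PPG)10"`),
  molecular formulas, monoisotopic masses, and an idealized PPII
  single/triple-helix builder with exact backbone dihedrals (φ = −75°,
  ψ = +150° by default) and L/D chirality.
- **Fragmentation** — cutting a labeled helix into partially overlapping
  fragments of 4 (or 7) amide units, offset by one amide, with hydrogen
  capping and an atom map back to the parent.
- **Cartesian tensor transfer** — moving per-atom property tensors (force
  constants; dipole, α, G′ and A derivatives) from fragments onto a
  distorted target geometry via best-fit local (Kabsch) rotations,
  stitching overlapping fragments into one consistent tensor set.
- **Vibrational spectra** — Eckart-projected harmonic normal modes,
  far-from-resonance backscattered SCP Raman/ROA invariants
  (90a² + 14β(α)², 48β(G′)² + 16β(A)² over c), Boltzmann weighting at
  300 K, unit-area Lorentzian convolution (FWHM 10 cm⁻¹), snapshot
  averaging, and normal-mode-subspace partial optimization.
- **Spectral analysis** — iterative polynomial baseline correction,
  normalization to the 1650 cm⁻¹ water band, CID and couplet statistics
  (CID₁, CID₂, Δ_CID = CID₁ − CID₂), prominence-based band detection, and
  a marker-band classifier (type I / type II / denatured I).
- **Conformation** — IUPAC backbone torsions, periodic Ramachandran
  free-energy surfaces (−k_B T ln n/n_max), triplet segment-length
  histograms.
- **Synthetic data** — seeded generators for spring force fields with
  closed-form oracles, chiral tensor sets calibrated to the 10⁻³ CID
  regime, experiment-like noisy spectra with fluorescence baselines, and
  PPII-concentrated von Mises dihedral trajectories. These stand in for
  the quantum-chemistry and molecular-dynamics engines, which are out of
  scope.
- **Pipeline** — `run_pipeline()` composes build → fragment → tensors →
  transfer → spectra → average → analyze with a JSON manifest and md5
  checksums; byte-reproducible under a fixed seed.
  `inst/scripts/roa-pipeline.R` is a thin shell wrapper.

## Worked example

```r
library(roacollagen)

s <- parse_triplet_notation("(PHG)9PHA")
s
#> peptide_sequence: 30 residues
#>   H-PHGPHGPHGPHGPHGPHGPHGPHGPHGPHA-OH
sequence_to_formula(s)
#> C121H174N30O41
monoisotopic_mass(sequence_to_formula(s))
#> 2703.2453
```

The formula and mass (2703.25 at 2 decimals) are what MALDI-MS reports for
this peptide. Spectral analysis of a synthetic collagen-I-like spectrum:

```r
fx <- normalize_to_water(collagen_fixture("type_I", seed = 1))$pair
couplet_stats(fx, c(1600, 1700))
#> couplet (-/+) in 1600-1700 cm^-1: CID1 = 0.000889 @ 1664,
#>   CID2 = -0.00194 @ 1630, delta_CID = 0.00283
score_collagen_type(fx)
#> collagen type score: type_I
#>   roa_473_positive             fired
#>   raman_306_339_doublet        -
#>   raman_221                    -
#>   amide_I_couplet_neg_pos      fired
```

The amide-I couplet is (−/+) from low to high wavenumber with lobe CIDs at
the 10⁻³ scale, and the classifier keys type I to the positive 473 cm⁻¹
ROA marker. An end-to-end simulation:

```r
cfg <- run_config(sequence = "(PHG)9PHA", n_chains = 3, window = 4,
                  n_snapshots = 10, seed = 1, outdir = "demo")
run_pipeline(cfg)
```

builds the triple helix, cuts 78 four-amide fragments, equips them with
synthetic chiral tensors, transfers the tensors onto 10 PPII-distorted
snapshots, synthesizes and averages backscattered Raman/ROA spectra, and
writes band tables plus a checksummed manifest (about a minute on one
CPU).

## Scope

DFT property-tensor calculation, production molecular dynamics, wet-lab
synthesis/HPLC protocols and spectrometer operation are out of scope; the
synthetic-data module supplies statistically comparable stand-ins for
their outputs. See the methods vignette
(`vignettes/collagen-roa-methods.Rmd`) for the model, parameter choices
and limitations.
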