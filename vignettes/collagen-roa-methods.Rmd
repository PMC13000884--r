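---
title: "Methods: simulating and analyzing ROA spectra of collagen-type peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing ROA spectra of collagen-type peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roacollagen)
```

## The problem

Collagen and collagen-type peptides fold into a right-handed superhelix of
three left-handed polyproline-II (PPII) strands. Raman optical activity
(ROA) — the difference between Raman scattering of right- and
left-circularly polarized light — reads out this chirality directly: the
amide-I carbonyl-stretch region shows a (−/+) couplet diagnostic of the
triple helix, and a positive ROA band near 473 cm⁻¹, assigned to the
4R-hydroxyproline ring, distinguishes collagen type I from type II. The
effect is small: circular intensity differences
CID = (I_R − I_L)/(I_R + I_L) are typically below 10⁻³.

Interpreting such spectra computationally follows a fragment-based
protocol: a large peptide is cut into overlapping fragments small enough
for quantum-chemical property calculations, the per-atom property tensors
of the fragments are transferred back onto the full molecule (and onto
conformational snapshots), and harmonic Raman/ROA spectra are synthesized
and averaged. This package implements every step of that protocol at desk
scale, replacing only the quantum-chemistry and molecular-dynamics engines
with seeded statistical generators.

## Peptide models

Sequences use the collagen triplet notation (P = Pro, H = Hyp, G = Gly,
A = Ala; a leading `D-` makes all chiral residues D). Formulas accumulate
residue compositions (Pro C5H7NO, Hyp C5H7NO2, Gly C2H3NO, Ala C3H5NO)
plus one water for the free termini; masses are monoisotopic (¹²C = 12
exactly, ¹H = 1.0078250319, ¹⁴N = 14.0030740052, ¹⁶O = 15.9949146221 Da).
Monoisotopic rather than average masses are used because the printed
reference values for these peptides match monoisotopic sums at two
decimals.

The helix builder grows heavy-atom backbones by internal coordinates
(NeRF placement) with ideal bonds N–Cα 1.46 Å, Cα–C 1.52 Å, C–N 1.33 Å,
C=O 1.23 Å and angles N–Cα–C 110°, Cα–C–N 116°, C–N–Cα 121°. Defaults are
the canonical PPII dihedrals φ = −75°, ψ = +150°, ω = 180°; every residue
receives exactly the requested values (round-trip measurement agrees to
10⁻⁶ degrees), and torsions follow the IUPAC sign convention, validated
against an independent frame-construction oracle. Side chains are rigid
local-frame templates; the proline ring is an idealized Cγ-endo pucker
closed numerically once (Cδ–N fixed at 1.47 Å), Hyp adds a 4R-hydroxyl at
C–O 1.41 Å. L residues are defined by a positive chirality determinant
det[N−Cα, C−Cα, Cβ−Cα], the convention found in experimental structures;
D residues mirror the side-chain template, so an all-D build at (−φ, −ψ)
is the exact reflection of the all-L build. Because only relative geometry
matters downstream, the builder is a stand-in for crystal-structure
coordinates, not a replica of any deposited entry.

For three chains, copies labeled A/B/C are placed on a triangle (radius
7 Å) around the common axis with a one-residue stagger. The chains are
translated copies rather than a re-derived coiled superhelix — adequate
for testing fragmentation, transfer and spectral synthesis, which is what
the triple-helix build exists for here.

## Fragmentation

An amide unit is the C, O of residue *i* plus the N of residue *i* + 1. A
window of *w* amide units (default 4; 7 also standard) slides by one
amide, giving M − w + 1 fragments per chain of M amides; a fragment owns
every residue contributing an atom to its window, side chains included.
Severed backbone bonds are capped with hydrogens at 1.09 Å along the
severed bond direction — the simplest valence-preserving scheme; the cap
atoms are flagged in the atom map and excluded from transfer. No criterion
privileges 4 over 7 amide units; both are exposed.

## Tensor transfer

Property tensors are per-atom Cartesian derivatives: the Hessian (mdyn/Å),
and derivatives of the dipole, the electric-dipole polarizability α, the
electric-dipole–magnetic-dipole tensor G′, and the
electric-dipole–electric-quadrupole tensor A with respect to atomic
displacement. For each atom of each fragment, a local best-fit (Kabsch)
rotation aligns the atom's neighborhood — itself plus its 12 nearest
mapped neighbors, ties broken by lower index, coordinates centered on the
atom — onto the target; improper best fits are never accepted silently
(the Kabsch construction always returns a proper rotation, and mirror
transfer must be requested explicitly through
`transform_tensor_set()`, which treats G′ as parity-odd). If source and
target neighborhoods are bitwise identical the rotation is the exact
identity, which makes self-transfer reproduce the input tensors exactly.

Per-atom tensors are averaged over all fragments containing the atom, each
contribution rotated on every Cartesian axis; Hessian 3×3 blocks (a, b)
average over fragments containing both atoms as R_a H_ab R_bᵀ, blocks for
never co-resident pairs are zero (long-range force constants dropped — an
explicit approximation), and the result is symmetrized. Fragment weights
are 1 + the atom's amide-unit distance from the nearer fragment edge, so
interior-of-fragment contributions dominate, mirroring the rationale for
overlapping fragments; pair weights take the minimum of the two atom
weights, and `"uniform"` weighting is available. Contributions are
accumulated already normalized (two passes), keeping single-fragment
self-transfer bit-exact. The exact weighting rule of the original
in-house transfer codes is not published; this rule is a documented
stand-in.

## Harmonic spectra

The mass-weighted Hessian is Eckart-projected: translations and rotations
(5 for collinear geometries, 6 otherwise) are removed with a projector
built by modified Gram–Schmidt. Modified Gram–Schmidt, unlike a pivoted QR,
is exactly equivariant under per-coordinate sign flips; combined with the
sign-equivariance of the LAPACK symmetric eigensolver this makes the whole
chain — modes, invariants, sticks, convolution — bit-for-bit
antisymmetric for enantiomeric inputs, so the mirror test (ROA negated,
Raman identical) passes at machine precision rather than at an
eigen-rounding tolerance. Frequencies are ν̃ = sign(λ)√|λ| × 1302.791
cm⁻¹ per √((mdyn/Å)/Da) (that constant is √(100 N·m⁻¹/amu)/(2πc));
imaginary modes are reported as negative wavenumbers, excluded from
spectra with a warning — stitched fragment Hessians on distorted
snapshots legitimately produce a few.

Per mode, the far-from-resonance invariants are
a = Tr α′/3, β(α)² = (3α′:α′ − Tr²α′)/2,
β(G′)² = (3α′:G′′ − Tr α′ Tr G′′)/2 and
β(A)² = (ω/2) α′_ij ε_ikl A′_klj, with ω represented by the excitation
wavenumber (532 nm → 18 796.99 cm⁻¹). Backscattered SCP stick weights are
S_p = k_p(90a² + 14β(α)²) and D_p = k_p(4/c)(12β(G′)² + 4β(A)²) with c
the speed of light in atomic units and
k_p = (ν̃₀ − ν̃_p)⁴/ν̃_p × [1 − exp(−hcν̃_p/k_BT)]⁻¹ (Boltzmann factor,
default 300 K). The global scale is arbitrary — only normalized shapes
and CID ratios are ever compared — but the S/D constant convention is
fixed as above so CID magnitudes are meaningful. Sticks are convolved
with unit-area Lorentzians (FWHM default 10 cm⁻¹) on a default 50–1800
cm⁻¹, 1 cm⁻¹ grid; a stick not covered by the grid ± 5 FWHM raises an
error unless the caller explicitly asks for a display window. Snapshot
averaging is an unweighted pointwise mean (whether the original protocol
weighted snapshots is unstated; equal weighting is implemented), and
averaging commutes with convolution by linearity.

Partial optimization restricted to a normal-mode subspace relaxes the
modes whose |ν̃| falls in a window while freezing the rest: Newton steps
with the reduced model Hessian (eigenvalue magnitudes floored for
non-positive curvature) and a backtracking line search, converged when the
maximum projected gradient drops below tolerance; frozen-mode projections
are unchanged by construction.

## Spectral preprocessing and statistics

Fluorescence backgrounds are removed by iterative polynomial fitting:
fit, clip points above the fit + 1σ of the residual, refit, until stable
(defaults degree 5, 50 iterations; non-convergence warns and returns the
last iterate). Raman intensities are normalized to the maximum in the
1630–1670 cm⁻¹ window around the 1650 cm⁻¹ water band — a window rather
than the exact point, robust to the ~7 cm⁻¹ instrument resolution — and
the paired ROA array is scaled by the same factor, which leaves every CID
unchanged.

Couplet statistics locate the extremal positive and negative ROA lobes in
a region (the evaluation points are a documented choice; the original
definition of the evaluation points is not printed): CID₁ at the
higher-wavenumber lobe, CID₂ at the lower, Δ_CID = CID₁ − CID₂, sign
pattern reported low→high. Negating the ROA array flips Δ_CID exactly.

Band detection uses topographic prominence on local extrema (positive and
negative separately for ROA). The classifier's effective threshold never
drops below six times a noise floor estimated from the median absolute
first difference, so a weak-signal ROA trace does not flood the band list
with noise peaks; in a marker-window-sized segment (~64 points of pure
noise) a 5σ prominence threshold yields zero bands in ≥95% of seeded
runs. Marker rules: R1 positive ROA at 473 ± 8 cm⁻¹ → type I; R2 Raman at
both 306 ± 6 and 339 ± 6 cm⁻¹ → type II; R3 Raman at 221 ± 6 cm⁻¹ →
denatured type I; R4 (flag only) amide-I (−/+) couplet →
triple-helix-consistent. Tolerances are set near the instrument
resolution — a design choice, not published values. The call is the
unique type whose evidence fires alone; conflicts give `indeterminate`.

## What the synthetic generators emulate — and what they do not

`make_spring_system()` builds mass-and-spring networks whose chain variant
has closed-form frequencies (free 1-D chain dispersion), used as an
oracle. `make_chiral_tensors()` equips a geometry with a rigid
distance-based spring Hessian (6 nearest neighbors per atom — enough
connections that exactly six zero modes remain) and random smooth tensor
derivatives; G′ is dominated by an α-correlated channel plus 25% noise and
A is scaled down by the excitation wavenumber, so the per-mode |ROA/Raman|
ratio stays within about a decade of its median; a final global scaling of
the chiral blocks sets that median exactly to `roa_scale` (default 10⁻³,
the experimentally typical CID regime). `make_experiment_spectrum()` sums
unit-area Lorentzians plus a broad 1650 cm⁻¹ water band, a polynomial
fluorescence baseline and Gaussian noise, returning the ground truth for
recovery tests; the four canonical fixtures (`type_I`, `type_II`,
`denatured_I`, `ambiguous`) encode the marker rules, with the denatured
fixture's amide-I couplet weakened fivefold so its Δ_CID is the smallest —
mirroring the experimentally observed ordering. Fixture noise defaults to
a high signal-to-noise regime (2×10⁻⁵ of the band scale), consistent with
multi-hour accumulation times. `make_ppii_trajectory()` samples per-residue
dihedrals from independent von Mises distributions (Best–Fisher sampler;
concentrations above 10⁸ are treated as the degenerate point-mass limit,
so the κ → ∞ trajectory is exactly the ideal helix) and rebuilds the chain
per snapshot.

Passing tests on these generators shows that the *machinery* — transfer,
normal modes, invariants, statistics, classification — is correct and
self-consistent. It does not show that real collagen spectra are
reproduced: the tensors are statistical, not quantum-chemical; the
dihedral distributions are independent rather than correlated; solvent,
anharmonicity and resonance effects are absent. Experimental band
positions and Δ_CID magnitudes printed for real samples are therefore
context, not targets.

## Numerical choices and problem sizes

Internal units are Da, Å and mdyn/Å with the single conversion constant
above. All RNG flows through per-generator seeds (`with_seed()` saves and
restores the global RNG state), making every artifact byte-reproducible;
the pipeline manifest records parameters and md5 checksums. Empty
Ramachandran bins carry +∞ (never extrapolated); bins are 10° × 10° by
default with periodic wrapping; free energies are −k_BT ln(n/n_max) in
kcal/mol. Segment length is defined Cα(i)→Cα(i+3) — the quantity is not
defined in print, so this is a documented choice. The test suite runs on
small systems (5–10-atom spring networks, 12–30-residue helices, 10⁴
dihedral samples) chosen so the full suite and the acceptance script each
complete in minutes on one CPU; the end-to-end demo uses a 30-residue
triple helix, window 4, and 10 snapshots. The tensor JSON container is
used for all cases at this scale; a binary container adds nothing at
desk-scale sizes.

## Known limitations

- The triple-helix arrangement is translational, not a re-wound
  superhelix; inter-chain Hessian couplings are zero because fragments
  never span chains.
- Stitched Hessians are not positive semidefinite; a few imaginary modes
  on distorted snapshots are expected and excluded from spectra (loudly).
- The baseline routine can hit its iteration cap on spectra with broad
  overlapping bands; it warns and returns the last iterate.
- Absolute Raman cross-sections are not calibrated; only normalized
  shapes and CID ratios are meaningful.
- No resonance-Raman or anharmonic corrections.
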