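---
title: "All-valence LCAO electronic structure and the tight-binding wire model of B-DNA charge transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{All-valence LCAO electronic structure and the tight-binding wire model of B-DNA charge transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lcaowire` computes the valence electronic structure of nucleic acid bases,
similar heterocycles, Watson-Crick base pairs and stacked base-pair dimers
with a semi-empirical linear combination of atomic orbitals (LCAO), and
condenses the result into the parameters of a nearest-neighbor
tight-binding *wire model* of charge transfer along a B-DNA stack.

Each molecular orbital is expanded in all valence atomic orbitals: 2s,
2px, 2py, 2pz on every C, N and O atom and 1s on every H atom. The
overlap matrix is approximated by the identity, so the problem is an
ordinary real symmetric eigenproblem. The Hamiltonian has three kinds of
matrix elements:

* **On-site energies** (diagonal): one fitted constant per element and
  shell (H 1s -13.64, C 2s -13.18, C 2p -6.70, N 2s -14.51, N 2p -9.55,
  O 2s -15.03, O 2p -11.52 eV). They are semi-empirical: fitted, in the
  parameterization adopted here, to the experimental ionization and
  excitation energies of the five nucleobases.
* **Covalent couplings** between *bonded* atoms: Slater-Koster
  two-center integrals assembled from the directional cosines of the
  interatomic unit vector with four radial channels
  `V_chi = chi * hbar^2 / (m d^2)` (Harrison's inverse-square form) and
  dimensionless prefactors chi_sssigma = -1.32, chi_spsigma = -1.42,
  chi_ppsigma = 2.22, chi_pppi = -0.73. Couplings between non-bonded
  atoms of the same molecule are zero.
* **Non-covalent couplings** between the two bases of a pair and between
  stacked monomers: the same angular structure, but the inverse-square
  radial law is replaced by an exponential decay
  `V_chi = chi * hbar^2/(m d0^2) * exp(-beta (d - d0))` with d0 = 1.35 A,
  a typical covalent bond length, because the inverse-square form is only
  valid at covalent distances while hydrogen bonds (about 2.9-3.0 A) and
  stacking contacts (3.4 A and beyond) are substantially longer.

Every matrix element involving an H 1s orbital is damped by a factor
b = 0.70, applied once per participating H orbital (so H-H couplings
carry b squared). Valence electrons (C 4, N 5, O 6, H 1) fill the
spectrum pairwise; minus the HOMO energy estimates the vertical
ionization energy and the HOMO-LUMO gap the first excitation energy.
Orbitals are classified as pi or sigma by projecting their p-coefficients
on the local base-plane normal, which keeps the pi-pi* reading of
ionization and excitation meaningful even for non-planar, deformed
geometries -- the reason for carrying all valence orbitals instead of a
pure pi (Huckel-type) basis.

Transition strengths use a point-dipole contraction: only same-atom,
same-orbital products contribute to the transition dipole, and the
oscillator strength is `f = (2/3) (E/E_h) (d/(e a0))^2` in atomic units.
Because distinct molecular orbitals are orthogonal, this dipole is
origin-independent.

# Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `onsite` | Table above | eV | per-element, per-shell diagonal energies |
| `chi` | -1.32, -1.42, 2.22, -0.73 | - | Slater-Koster channel prefactors |
| `b` | 0.70 | - | damping per participating H orbital |
| `d0` | 1.35 | A | reference covalent length of the exponential regime |
| `beta` | 2/d0 = 1.4815 | 1/A | non-covalent decay rate |
| `scale` (bond perception) | 1.15 | - | tolerance on covalent radii sums |
| `cross_cutoff` | 10 | A | non-covalent coupling cutoff |
| rise, twist | 3.4 A, 36 deg | | ideal B-DNA step |

**The beta knob.** The typeset form of the exponential decay admits two
readings: a rate of `2/d0` per Angstrom or an absolute rate of `2` per
Angstrom. Both are implemented behind the `beta` argument of
`lcao_params()`. The package default is `2/d0`: calibrating once against
the stacked-dimer hole transfer integrals (the GG and TC steps of the
ideal-geometry transfer table) gives 66 and 109 meV with `beta = 2/d0`
versus 31 and 46 meV with `beta = 2`, so the `2/d0` reading is decisively
closer to the reference values (116 and 142 meV) and is frozen for every
other computation in the package. Whether `b` also damps non-covalent
couplings involving H is likewise not uniquely specified; it is applied
uniformly in both regimes here.

**Bond perception.** "Neighboring atoms" is realized as the standard
chemistry criterion: bonded iff the distance is at most 1.15 times the
sum of covalent radii (H 0.31, C 0.76, N 0.71, O 0.66 A). This
reproduces the ring connectivity of all packaged molecules (for example
16 bonds for adenine: 15 atoms + 2 rings - 1). Distances under 0.4 A are
rejected as clashes.

# Geometries: what the generators emulate

The paper-style workflow needs three kinds of geometry, and all three
are generated by code (nothing binary is shipped):

* **Single bases** (`nucleobase()`): planar heavy-atom geometries in the
  standard base-pair reference frame (the widely used crystallographic
  consensus geometry of each base), with the sugar replaced by an H cap
  on the glycosidic nitrogen and all hydrogens placed geometrically (N-H
  1.01 A, aromatic C-H 1.08 A along external bisectors, planar amino
  groups, tetrahedral methyl for thymine). All atoms lie in z = 0 except
  thymine's two out-of-plane methyl hydrogens.
* **Watson-Crick pairs** (`wc_pair()`): the leading-strand base in
  standard orientation plus its complement reflected through
  (y, z) -> (-y, -z). Because the standard frame is defined on the
  paired configuration, this brings the hydrogen-bonding faces together
  at donor-acceptor distances of 2.9-3.0 A with no optimization step.
* **Ideal dimers** (`ideal_dimer()`, `build_ideal_dimer()`): the second
  pair rotated by the helical twist about the global z axis through the
  origin and translated by the rise. Defaults 3.4 A and +36 degrees
  (right-handed). The twist axis is taken through the standard-frame
  origin; real B-DNA has a small x-displacement of the pairs from the
  helix axis, which is one of the reasons stacked-dimer couplings are
  geometry-sensitive (below).
* **Heterocycles** (`fixture_molecule()`): thirteen additional planar
  heterocycles (purine tautomers, diazines, azoles, fused bicyclics)
  shipped as XYZ text generated with a standard force-field pipeline
  (ETKDG embedding + MMFF94 minimization); each file is labelled a
  synthetic geometry in its comment line.

MD-deformed monomers and dimers are *inputs*, not fixtures: users prune
base pairs from snapshot PDB files (`read_pdb()`, `select_residues()`)
and feed them to the same machinery. No trajectory formats and no MD
engine are provided.

What the generated geometries do **not** emulate: sugar-phosphate
backbone polarization, solvent and counterions, thermal vibrations, and
the source paper's own (unpublished) coordinates. Tests that pass on
these fixtures therefore validate the *method* -- its invariances, limits
and closed forms exactly, and its printed benchmark numbers to the
stated energy tolerances -- but absolute transfer integrals for stacked
dimers remain sensitive to geometry details at the tens-of-percent
level, as the structural-variability analysis itself demonstrates.

# Base-pair structural parameters

The six intra-pair parameters (shear, stretch, stagger in Angstrom;
buckle, propeller twist, opening in degrees) are computed natively.
Each base's frame is obtained by least-squares (Kabsch) superposition of
its standard reference geometry onto the observed coordinates using the
six-membered-ring atoms; the frame is the image of the standard frame
(x toward the major groove, y toward the leading-strand sugar, z along
the normal, anti-parallel between the two bases of a pair). The base-2
frame is flipped (y, z negated), the mid-frame is the half-way rotation
between the two frames, translations are the components of the
inter-origin vector in the mid-frame, and rotations are the components
of the angle-times-axis vector of the frame-2-to-frame-1 rotation along
the mid-frame axes. An undistorted pair gives exactly (0, 0, 0, 0, 0, 0).
Under swapping the two bases, shear and buckle change sign and the other
four parameters are preserved -- the same symmetry as the field's
standard implementations. The exact atom set used by the reference
web tools is not published; this convention is documented, not claimed
byte-identical, and pure-displacement tests pin its signs (for example,
rotating base 2 by +10 degrees about the shared y axis yields propeller
-10 degrees).

# The wire model

For a stack of N monomers (base pairs), `build_wire_from_dimers()`
solves each monomer, takes its HOMO (holes) or LUMO (electrons) energy
as the site energy E_alpha, and contracts the frontier orbitals of
consecutive monomers with the non-covalent coupling blocks to get the
transfer integrals t_alpha,alpha+1:

```
t = sum_{i nu, j mu} c(1)_{i nu} V_{i nu, j mu} c(2)_{j mu}
```

The resulting chain Hamiltonian is strictly nearest-neighbor (no
second-neighbor hops even for deformed geometries -- a model choice, not
an approximation made for convenience). Orbital phases after
diagonalization are arbitrary, so the sign of t is convention-dependent
(largest-magnitude coefficient positive); reports quote |t|.

Two quantities summarize a dimer: Delta, the difference of the two
monomers' frontier energies (monomer 1 minus monomer 2 in 5'-3' order),
and the maximum transfer percentage

```
p = (2t)^2 / ((2t)^2 + Delta^2),
```

the peak probability of finding a carrier on the monomer where it did
not start. For identical monomers in ideal geometry Delta = 0 and p = 1
exactly. `propagate()` evolves site amplitudes with the spectral
propagator (hbar = 0.6582119569 eV fs), which conserves the norm and
energy to round-off; the two-site evolution reaches exactly p, which is
the package's own cross-check between the transfer module and the
dynamics. Coherent transport (transmission through contacts) is out of
scope; the module stops at eigenspectra and coherent dynamics.

# Numerical choices and degenerate inputs

* Diagonalization by `eigen(symmetric = TRUE)`; eigenvalues ascending;
  eigenvector phase fixed by the largest-coefficient-positive rule.
* Overlap = identity exactly; no Lowdin orthogonalization.
* The 10 A non-covalent cutoff changes couplings by less than 1e-5 of
  their contact value -- numerically inert, kept only to bound the work.
* Frontier degeneracies within 1e-6 eV set a `degenerate_frontier` flag
  rather than erroring; downstream transfer reports include
  near-degenerate channels (within 0.05 eV of the frontier level, a
  window argument) as extra rows instead of silently picking one.
* Odd-electron systems, clashing atoms (< 0.4 A), sub-0.4-A two-center
  distances, collinear frame atoms and non-normalized initial wire
  states raise errors naming the offence.
* Atomic-unit constants: 1 hartree = 27.211386 eV, 1 bohr = 0.529177 A,
  hbar^2/m = 7.6199682 eV A^2.
* Indices are 1-based throughout, as idiomatic in R; file formats are
  the standard two-header XYZ dialect and fixed-column PDB ATOM/HETATM
  records (element from columns 77-78, falling back to the first
  alphabetic character of the atom name).

# Validation strategy and problem sizes

The test suite works in two tiers. Tier 1 checks exact properties:
rotational/translational invariance of spectra (100 random rigid motions
of adenine, 10 of a full G-C pair, drift under 1e-8 eV), element-wise
agreement of the pi sector of exactly planar molecules with an
independently assembled pure-pi matrix (1e-12 eV), the inverse-square
and exponential radial laws over distance sweeps, two-site dynamics
against the closed-form p on a (t, Delta) grid (1e-10), and uniform-chain
eigenvalues against the open-chain closed form up to N = 50 (1e-10).
Tier 2 regresses printed benchmark numbers on the packaged geometries:
nucleobase ionization and excitation energies and adenine's oscillator
strength, pair HOMO energies, the GG and TC hole transfer integrals, and
the two root-mean-square percentage errors versus experiment. These
sizes (molecules up to 45 basis functions, pairs 87-90, dimers about
180) keep the whole suite under a minute on one CPU.

# Known limitations

* No self-consistency or charge relaxation; no elements beyond C, N, O,
  H; no d orbitals.
* Discrete transition energies and oscillator strengths only -- no band
  shapes.
* No environment corrections (solvent, counterions) and no transfer
  rates (Marcus theory); the outputs are bare tight-binding matrix
  elements.
* Absolute stacked-dimer transfer integrals inherit the geometry
  sensitivity discussed above: with the package's ideal-geometry
  convention the GG hole coupling comes out at 66 meV, below the 87-145
  meV band implied by the reference table, while TC (109 meV), the pair
  energies and the molecular benchmarks all land inside their bands.
  Published couplings for the GG step span roughly 50-120 meV across
  methods and geometry choices, so users comparing against a specific
  reference should use that reference's coordinates rather than the
  ideal generator.
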