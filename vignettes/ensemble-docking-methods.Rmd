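---
title: "Ensemble docking of flexible receptors and DNA aptamers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble docking of flexible receptors and DNA aptamers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptadock)
```

## The problem

A homodimeric growth-factor-like receptor carries two globular domain types
per monomer — a receptor-binding domain (RBD) and a heparin-binding domain
(HBD) — joined by a flexible linker. Because the linker is disordered, the
dimer has no single representative structure: the two HBDs swing over
nanometres, and any docking calculation against one frozen conformation
misses most of the accessible binding geometries. The same applies to
heterodimeric DNA aptamer ligands, two aptamer units joined by a flexible
oligo-dT linker. `aptadock` implements the resulting *ensemble docking*
strategy: sample the large-scale motion of both partners explicitly,
cross-dock every receptor conformer against every ligand conformer, filter
by which domains each aptamer unit must engage, re-score, and analyse the
surviving complexes geometrically.

All internal lengths are nm; PDB I/O converts to and from angstrom, and
H-bond distances/RMSDs are reported in angstrom because those criteria are
conventionally quoted in that unit.

## Stage 1 — collective motion from an elastic network

`build_enm()` places one node per residue (C-alpha for protein, the
backbone phosphate node for DNA) and connects all node pairs within a
cutoff by identical springs. The Hessian block for a connected pair is
`-gamma (r r^T)/|r|^2`; diagonal blocks enforce the zero-row-sum identity,
so translations are exact null vectors and a connected network has six
near-zero (rigid) modes. `compute_modes()` diagonalises the Hessian
densely. The package always uses the dense symmetric eigensolver: the
largest network it builds (the default receptor, 354 nodes, 1062
coordinates) diagonalises in about a second, and no supported workflow
exceeds a few thousand coordinates, so an iterative shift-invert path
would add a dependency without a workload.

Parameter choices, all overridable:

* `cutoff = 1.5` nm — a common residue-level elastic-network radius that
  keeps mixed protein/DNA networks connected at our bead spacing;
* `gamma = 1` (arbitrary energy/nm²) — the spring constant scales all
  eigenvalues uniformly and cancels in mode shapes, so its value is
  immaterial for everything downstream;
* `rigid_tol = 1e-8` relative — classifies rigid modes.

`mode_distance_overlap()` scores each mode by the absolute cosine between
the mode vector and the gradient of the HBD1–HBD2 centre-of-mass distance;
the mode that maximises it is the "scissoring" motion that opens and
closes the two HBDs. On the synthetic receptor this is the lowest
non-rigid mode, which the test suite asserts (among the lowest three).

## Stage 2 — conformer ensembles at prescribed distances

Reference protocols realise target inter-domain distances with biased
molecular dynamics (a harmonic centre-of-mass restraint of 1000
energy-units/nm², snapshots every few hundred ps). The only role that
machinery plays for docking is to produce conformers *at* the target
distances, decorated with small thermal fluctuations. `aptadock` replaces
it with a deterministic surrogate — the central modelling substitution in
the package:

1. `drive_to_distance()` displaces coordinates along the maximal-overlap
   low mode, solving the quadratic `|c0 + t w| = target` for the amplitude
   exactly, then relaxes in the subspace of the 10 lowest non-rigid modes
   by minimising `½ Σ λ_i a_i² + ½ k (d(a) − target)²` with `k = 1000`,
   the same restraint constant the biased protocol uses (BFGS with
   analytic gradient). Atoms move rigidly with their residue's node.
2. `generate_ensemble()` walks a `distance_grid()` (receptor 3–9 nm step
   1 nm; heterodimer 2.0–7.5 nm step 0.5 nm), stores the driven structure
   as snapshot 0, and adds seeded random superpositions of the low modes
   (RMS node amplitude `perturb_amp = 0.1` nm) as the remaining
   snapshots, each re-restrained to the target by a closed-form
   correction along the driving mode.

With 20 snapshots per grid point the canonical counts follow exactly:
7 × 20 = 140 receptor conformers and 12 × 20 = 240 heterodimer conformers.
Monomeric aptamers get unrestrained `free_ensemble()` snapshots (20 each).
`dist_tol = 0.05` nm is the acceptance band on achieved distances; in
practice the restrained minimisation lands within ~1e-3 nm. Because the
displacement field is linear in mode amplitudes, large drives shear local
geometry slightly — acceptable here because every downstream consumer
(grid docking, contact filters, end-point rescoring) tolerates
bond-length noise far larger than this, but it is why the surrogate makes
no thermodynamic claims: snapshots are *geometric* stand-ins, not Boltzmann
samples, and their independence across snapshots is an assumption, not a
simulation result.

## Stage 3 — FFT rigid docking

`dock()` follows the classic two-stage shape-complementarity protocol:

* **Rotations.** `sample_rotations()` builds a deterministic quasi-uniform
  SO(3) grid in Hopf coordinates (Fibonacci axis lattice × evenly spaced
  circle angles) sized to a requested geodesic interval; 15° gives 576
  rotations including the identity. Production settings are 15° and
  0.12 nm grid spacing; a coarse preset (≥30°, 0.3 nm) keeps tests and
  demonstration campaigns fast.
* **Translations.** `grid_project()` digitises heavy atoms onto a cubic
  lattice (cell occupied if its centre falls inside an element-radius
  sphere). Receptor cells with all six neighbours occupied form the
  *core* and carry the imaginary weight `9i` (the classic
  Katchalski-Katzir penalty); the remaining occupied cells are *surface*
  with weight 1; the ligand is all-ones. `fft_translate_score()` computes
  the correlation over all lattice translations with one 3-D FFT per
  rotation and scores `Re − Im`, i.e. surface contact minus nine times
  the core overlap. The exported digitiser enforces the strict
  "structure fits the grid" contract; internally the rotated ligand is
  projected with periodic wrapping, which is safe because the box is
  sized for receptor extent plus ligand diameter plus clearance, so no
  contacting placement wraps.
* **Re-scoring.** The knowledge-based potential used by the reference
  docking engine is proprietary; in its place the ten best translations
  per rotation are re-scored with a documented soft contact potential
  (`pair_potential()`: +1 per heavy-atom pair in the 0.3–0.6 nm shell,
  −20 per pair under 0.25 nm) and the best re-scored translation is kept
  per rotation. No continuous pose optimisation is performed after
  re-scoring. Ties break lexicographically (rotation, then translation
  index), making the ranked output fully deterministic.

## Stage 4 — attachment criteria and selection arithmetic

A *contact* between a receptor group and a ligand group means at least one
(protein side-chain heavy atom, DNA heavy atom) pair within 0.45 nm.
`attachment_filter()` demands that the RBD-binding aptamer unit contact
the RBD pair and the HBD-binding unit contact the HBD pair (a monomer
needs only its own role satisfied). The reference workflow applied this
exclusion manually by inspection; formalising it with the same 0.45 nm
rule used for pose classification is this package's declared
operationalisation. `select_top_k()` then keeps the top-3 passing poses
per variant pair; groups with fewer passing poses keep what they have.
`manifest_counts()` carries the closed-form bookkeeping: 140 × 240 =
33 600 docked pairs and 84 variant pairs per heterodimer (252 selections),
140 × 20 = 2 800 and 21 per monomer, and 2 × 252 + 3 × 21 = 567 for the
canonical five-ligand roster. Internally "higher score is better";
engines reporting negative-better scores should be sign-flipped at import.

## Stage 5 — MM/GBSA-style end-point rescoring

`binding_free_energy()` evaluates, per snapshot,
`ΔG = ΔE_MM + ΔG_GB + ΔG_SA` in the single-trajectory scheme: bound and
free states share coordinates, so intramolecular mechanics cancels and
only receptor–ligand Coulomb (no cutoff, `k_e = 332.0636`
kcal·Å·mol⁻¹·e⁻²) and 12-6 Lennard-Jones terms are computed. The entropy
term is omitted, as is common for comparative end-point estimates.
Solvation uses:

* **Polar:** Still-form pairwise generalized Born with
  `f_GB = sqrt(r² + R_i R_j exp(−r²/4R_iR_j))`, effective radii from
  HCT-style pairwise descreening (scale 0.8, radii capped at 30 nm),
  `ε_in = 1`, `ε_out = 78.5`, no salt. A single ion reproduces the Born
  formula analytically and two distant unit charges the screened-Coulomb
  limit; both are frozen into the tests.
* **Nonpolar:** `γ·SASA` with `γ = 0.0072` kcal·mol⁻¹·Å⁻² and zero
  offset, the classic choice. `sasa()` is a deterministic Shrake–Rupley
  implementation on a Fibonacci sphere (default 256 points/atom; campaign
  stages use fewer because only differences of large areas enter ΔG).

The parameter table (`ff_lite()`) is deliberately small: element radii and
Lennard-Jones parameters plus formal integer charges (phosphate −1,
Lys/Arg +1, Asp/Glu −1). Explicit per-atom `charge`/`gb_radius` columns
override it, which is how closed-form test systems are constructed. With
this parameterisation ΔG values *rank* poses and ligands; they are not
comparable to published absolute binding free energies computed with full
force fields, and the package does not attempt that comparison.

## Stage 6 — geometric analysis

* **H-bonds** (`detect_hbonds()`): intermolecular donor–H⋯acceptor
  triplets with donor–acceptor distance ≤ 3.5 Å and H–donor–acceptor
  angle ≤ 30° — the angle at the *donor*, exactly as the criterion is
  stated, not donor–H–acceptor linearity. Donors lacking an explicit
  hydrogen are skipped and counted. `hbond_census()` averages per-residue
  multiplicities (not binary presence) over snapshots for the seven RBD
  key residues and ten basic HBD key residues, per chain.
* **Pose taxonomy** (`classify_pose()`): evidence is the 0.45 nm contact
  matrix of aptamer units × receptor domains. Precedence: *sandwich* if
  any single unit touches both HBDs; else *hug* if the RBD-binder is
  wedged against both RBDs while the HBD-binder touches exactly one HBD;
  else *side* if the HBD-binder touches exactly one HBD and the
  RBD-binder at most one RBD; else unclassified. The prose notions
  "interior" and "outside" are operationalised as touching both versus at
  most one unit of the domain pair; for monomers, clauses about the
  absent unit hold vacuously (so a monomer bridging both HBDs is a
  sandwich and an RBD-monomer wedged between both RBDs is a hug). The
  precedence order resolves overlapping evidence deterministically.
* **Quadruplex stability** (`quadruplex_rmsd_distribution()`): Kabsch
  RMSD of the 12-residue quadruplex core's heavy atoms against the stored
  reference per snapshot, histogrammed at 0.25 Å bins. The core size is
  enforced at 12 unless explicitly overridden.
* **Steric clash with the natural partner** (`clash_area()`): the complex
  is superposed onto a reference receptor by Kabsch fit of an alignment
  group's backbone nodes, the aptamer is transplanted, and the buried
  area against the reference partner is `(SASA_A + SASA_B − SASA_AB)/2`.
  The half convention matches interface-area servers; `half = FALSE`
  yields the total SASA loss.
* **Superposition** (`kabsch_rmsd()`): SVD Kabsch with the determinant
  correction, so reflections are never returned.

## The synthetic generators

Everything above is exercised on seeded synthetic structures
(`make_toy_receptor()`, `make_toy_aptamer()`), built to reproduce the
*topology* the method depends on rather than chemistry:

* globular domains are self-avoiding beads on a jittered FCC lattice
  (spacing 0.55 nm) inside a sphere — 110 residues per RBD, 55 per HBD,
  mirroring a 165-residue monomer with a 12-residue interdomain linker;
* linkers are slack Bezier chains, arced out of the scissor plane so the
  distance-coupled HBD swing remains the softest motion;
* every residue carries a backbone node, radially pointing pseudo
  side-chain heavy atoms, an annotated acceptor, and an annotated donor
  with an explicit hydrogen, so contact and H-bond machinery have
  realistic targets; protein chains are built net-neutral while DNA
  carries one formal negative charge per residue;
* the quadruplex-core monomer stacks three 4-residue rings (three quartet
  planes) whose reference coordinates are stored for RMSD analysis; the
  heterodimer joins a quadruplex unit and a plain unit with ten thymine
  linker residues; a locked-nucleic-acid variant differs only by a
  residue tag;
* `make_pose_fixture()` and `make_hbond_fixture()` construct complexes
  whose classification and H-bond counts are known *by construction*,
  giving the analysis layer ground truth; the pose fixtures use a reduced
  HBD separation (3.4 nm, inside the 3–9 nm conformer window) so a rigid
  aptamer unit can physically bridge both HBDs.

What the generators deliberately do not emulate: real nucleotide and
side-chain geometry, sequence-dependent energetics, solvent, and
counterions. Consequently, green tests demonstrate that the *pipeline
machinery* is correct (arithmetic, filters, scores, invariants,
closed forms) — not that the method's biological predictions transfer to
real molecules, which would require the original structures and force
fields.

## Execution modes and problem sizes

`run_campaign()` runs the staged flow end to end. In `fixture_mode`
(default) the docking stage is replaced by labelled pose fixtures so the
full selection arithmetic — 33 600 enumerated pairs per heterodimer, 567
selections over the five-ligand roster — executes in seconds; scores per
variant are seeded jitter, which exercises grouping, filtering and
top-k selection without the docking cost. The full mode really docks
every conformer pair and is intended for scaled-down configurations (the
shipped example uses a 30-residue-per-monomer receptor, two grid points,
one snapshot, 90° rotations at 0.3 nm spacing). The test suite follows
the same sizing policy: closed-form oracles at full precision, campaign
arithmetic at canonical size, docking and energetics on reduced systems.

## Numerical choices and degenerate inputs

* COM distances use unweighted heavy-atom centroids; with near-uniform
  pseudo-atoms, mass weighting would move either centroid by less than
  the bead spacing.
* Time labels from the emulated protocols (500 ps snapshots, 10 ns runs)
  are metadata only; `snapshot_index` replaces time.
* Eigen-spectra clamp round-off negatives at zero; rigid modes are
  counted against `1e-8 ×` the largest eigenvalue.
* An unreachable distance target errors with the best achieved value; a
  disconnected elastic network warns and yields more than six near-zero
  modes rather than failing.
* Docking ties break by (rotation, translation) index; selection ties by
  pose id — both total orders, so every ranked output is reproducible.
* altloc records other than blank/'A' are dropped on read; insertion
  codes, hybrid-36 numbering, mmCIF and multi-model files are out of
  scope.

## Known limitations

ΔG values are comparative only (minimal parameter table, no entropy, no
salt); conformers are geometric surrogates for biased sampling; the
re-scoring potential stands in for an unpublishable knowledge-based
function; clash areas depend on a synthetic reference partner unless a
real one is supplied. Within those bounds every number the package
reports is deterministic under a seed and covered by an oracle or
invariant in the test suite.
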