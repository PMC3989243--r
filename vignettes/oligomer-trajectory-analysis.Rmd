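---
title: "Quantifying beta-sheet oligomer (de)stabilization from trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-sheet oligomer (de)stabilization from trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotraj)
```

## The scientific problem

Small beta-sheet-rich oligomers of amyloidogenic peptides — human islet
amyloid polypeptide (hIAPP, amylin) is the motivating system — are held
together by a cross-beta lattice: each 37-residue chain folds as
beta-strand (residues 1–17) – turn (18–27) – beta-strand (28–37), and
chains stack in register about 4.8 Å apart along the fibril axis, zipped by
inter-chain backbone hydrogen bonds. Small polyphenols such as EGCG can
destabilize these assemblies. Deciding *whether* a simulated oligomer
stays ordered, *where* its beta structure is lost, and *where* a ligand
binds requires a standard battery of trajectory statistics. `oligotraj`
implements that battery as a coherent package, together with a synthetic
trajectory generator that provides ground truth for every statistic.

## The statistics and their definitions

**Nematic order parameter.** Each chain contributes a unit vector
$u_i$ from the C$\alpha$ of its first residue to the C$\alpha$ of its
last. The ordering tensor
$Q = \tfrac{1}{N}\sum_i \left(\tfrac{3}{2} u_i u_i^\top - \tfrac12 I\right)$
is diagonalized; the director $d$ is the eigenvector with the largest
eigenvalue and
$P_2 = \tfrac{1}{N}\sum_i \left(\tfrac{3}{2}(u_i\cdot d)^2 - \tfrac12\right)$
equals that eigenvalue. The construction of the director is the standard
liquid-crystal estimator: it makes $P_2$ well defined, maximal over all
unit directors, and confined to $[0,1]$. A system is called *ordered*
when mean $P_2$ strictly exceeds 0.5, the conventional cutoff for
fibril-like peptide assemblies; the boundary itself is classified
disordered.

**Hydrogen bonds.** A donor–hydrogen–acceptor triple is a hydrogen bond
when the donor–acceptor distance is strictly less than 3.5 Å and the
D–H–A angle strictly exceeds 150°. Both inequalities are strict; donors
are N/O atoms with an explicitly parented hydrogen, acceptors are N/O.
Structures without hydrogens are refused rather than rebuilt — hydrogen
placement is out of scope. The inter-peptide backbone H-bond count is the
fibril-integrity monitor; residue-pair maps for a chain pair are
accumulated over an analysis window and normalized so the largest cell
equals 1.

**Secondary structure.** Assignment is "STRIDE-like" in its output
alphabet (H, G, E, B, T, C) but is built from hydrogen-bond topology plus
a geometric turn rule, not from STRIDE's unpublished dihedral propensity
constants: helices from two consecutive i→i+4 (or i+3) backbone bonds,
extended strands from bridges (inter-chain H-bonds, or intra-chain at
sequence separation ≥ 5) that stack into ladders, isolated bridges as B,
turns from single i→i+3/i+4 bonds or backbone reversal
(C$\alpha_i$–C$\alpha_{i+3}$ < 7 Å, which covers the U-bend where
H-bond-only rules under-call turns), and coil otherwise, with priority
H > G > E > B > T > C. Beta content is (#E + #B) divided by the total
residue count; a flag restricts it to E only. Exact STRIDE parity is a
non-goal; on idealized lattices the assignment is exact by construction.

**Free-energy landscape.** For reaction coordinates we use the
per-frame beta content (fraction) and radius of gyration (reported in nm
on the landscape axis, Å everywhere else). The 2-D histogram on a grid
padded 2 % beyond the data range is converted by
$\Delta G = -k_\mathrm{B}T \ln(P/P_{\max})$, so the most populated bin is
exactly 0 and empty bins are $+\infty$
($k_\mathrm{B} = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$, default
$T = 310$ K). Basins are local minima over the 8-neighborhood, kept
deepest-first with a minimum pairwise bin separation (ties broken toward
lower beta content, then lower Rg). Default grid 40×40; the worked
analyses in this package use coarser grids (10–30 bins per axis) matched
to their frame counts so that bin occupancies stay in the tens.

**Clustering.** Conformations are superposed onto the first frame
(Kabsch least squares over protein C$\alpha$, reflections excluded) and
partitioned by k-medoids on the pairwise RMSD matrix with seeded
initialization. k-medoids replaces self-organizing-map clustering used in
older toolchains because the latter's grid topology and learning schedule
are not reproducible; k-medoids on the same metric is deterministic for a
fixed seed, and its medoid representatives are verifiable against brute
force. Duplicate frames that collapse two medoids are merged with a
warning and the surplus cluster reported empty. Stability is assessed by
re-clustering at several k and comparing the cumulative occupancy of the
top two clusters.

**Ligand contacts, sites and energies.** A residue is contacted when any
of its backbone (or sidechain) heavy atoms lies strictly within 3.5 Å of
any ligand atom; protein hydrogens are excluded by default because the
convention "an atom of one residue" is ambiguous, and a flag flips this.
Contact probability is the fraction of window frames with a contact;
residues above probability 0.1 are flagged important. A ligand is
site-forming when, in at least half of the window frames, its
contacted-residue set has Jaccard overlap ≥ 0.5 with its consensus set
(residues contacted in ≥ 50 % of frames); site-forming ligands whose
consensus sets overlap at Jaccard ≥ 0.5 merge into one site. Sites are
ranked by mean ligand–protein interaction energy, most negative first.
The energy is a plugin-style pairwise sum: Coulomb
$332.0636\, q_i q_j / r$ plus 12-6 Lennard-Jones with Lorentz–Berthelot
combining, both multiplied by the CHARMM-form switching function that is 1
up to 10 Å, 0 beyond 12 Å, and C¹-continuous in between. No periodicity,
no solvation. Pi-stacking pairs are reported when ring centroids are
within 5.5 Å and classified parallel (< 30° between best-fit ring
normals), perpendicular (> 60°) or tilted; these thresholds are the
community-standard geometric values, since the underlying study names the
interactions without stating criteria.

## The synthetic generator: what it emulates and what it does not

`build_ordered_oligomer()` lays backbone atoms (N, H, CA, C, O, plus one
CB-like pseudo-sidechain per non-Gly residue of the hIAPP 1–37 sequence)
on an idealized single-layer, parallel, in-register U-bend lattice:
3.4 Å rise per strand residue, 4.8 Å chain stacking, the two strand
sheets 12 Å apart joined by a semicircular turn. Amide N–H groups of
strand residues point along the stacking axis with the acceptor carbonyl
placed 2.9 Å away on the same line, so every inter-chain backbone H-bond
(N···O = 2.9 Å, D-H-A = 180°) holds *by construction* — the template is
an H-bond-lattice scaffold with correct topology, not stereochemistry.
The lattice constants are standard cross-beta values. Only a single layer
is supported.

`generate_trajectory()` perturbs the template independently per frame:

* `ladder_break_fraction` — each constructed inter-chain H-bond geometry
  is broken with this probability by rotating the donor amide hydrogen
  out of alignment, leaving everything else intact, so the surviving
  bond count is known exactly per frame (the `ground_truth` attribute);
* `orientation_sigma` — a random rigid rotation of each chain about its
  centroid (angle ~ N(0, σ) degrees, random axis), degrading P2 and, more
  steeply, beta content;
* `fray_terminal` — random displacement of the last k residues of the two
  edge chains, emulating C-terminal fraying.

Frames are independent draws: every analysis in scope is an ensemble
statistic, so temporal correlation is deliberately absent. Consequently
passing tests say nothing about kinetics, convergence diagnostics on real
MD, solvent effects, or force-field quality — they establish that each
estimator returns the right value when the answer is known.

Rigid ligands are polyphenol *caricatures*: one to three flat
six-membered rings with hydroxyl donors and ester/carbonyl acceptors,
near-zero partial charges and small Lennard-Jones radii chosen so that
every surface contact beyond the 2.5 Å exclusion shell is attractive —
which makes the group energy scale with how much of the molecule is
buried. They are not parameterized real molecules; real coordinates and
charges enter as a user template. Anchored copies are docked once against
an anchor residue along the local outward surface normal (smallest
principal component of the protein patch within 8 Å, signed toward the
emptier side), then carried through the trajectory by the anchor chain's
rigid motion, guaranteeing persistent detectable contacts; copies with
`site = NULL` are re-scattered on a distant shell every frame and never
persist. The `tilt` parameter fixes the docked ring-plane angle, and the
template's `rings` count fixes the molecular footprint; together they are
the generator's levers for constructing binding sites of known,
decreasing contact density.

## Numerical and design choices

* Strict inequalities at both H-bond thresholds and the contact cutoff.
* The donor–acceptor (not H–acceptor) distance enters the H-bond rule.
* Chain end-to-end vectors use C$\alpha$ of residues 1 and 37; heavier
  alternatives were rejected as noisier.
* Superposition uses base `svd()` with a reflection guard; RMSD/RMSF
  default to all protein C$\alpha$ with the first frame as reference, and
  RMSF refuses un-superposed trajectories rather than silently fitting.
* RMSF is averaged across chains at equal residue index; error bars on P2
  are plain standard deviations over frames (per-chain alternatives are
  not implemented).
* The analysis window defaults to the last half of the trajectory, the
  usual equilibrated-tail convention; every windowed function takes an
  explicit `frame_window`.
* Occupancies of specific H-bonds are keyed by donor/acceptor *atom*
  pair (any hydrogen); residue-pair aggregation is available through the
  map machinery.
* FEL zero-variance axes collapse to a single bin with a warning;
  all-zero H-bond maps skip normalization and carry a flag.
* k-medoids assignment ties go to the lowest cluster index and medoid
  ties to the lowest frame index, making results reproducible
  bit-for-bit for a fixed seed.
* PDB is the one required trajectory dialect (multi-model, via bio3d);
  binary formats are out of scope, as are PSF/PRMTOP parsing, hydrogen
  reconstruction and periodic-boundary handling.

## Problem sizes used in the shipped analyses

The packaged tests and the study script run pentamers (5 × 37 residues,
about 1 100 atoms) with 10–200 frames per condition, 5 seeds for
monotonicity checks, 40–80 frames for landscape and clustering
demonstrations, and 15–50 frames for ligand-site studies. These sizes
give bin occupancies and contact statistics large enough for the
properties under test while keeping every analysis in the seconds-to-
minutes range on one CPU.

## Known limitations

* The secondary-structure assignment is topology-based; it will not
  reproduce STRIDE or DSSP outputs residue-for-residue on real proteins.
* The generator's disorder is frame-independent; autocorrelated observables
  (RMSD drift, convergence plots) on generated data look like white noise
  around a mean rather than like relaxing MD.
* Interaction energies are vacuum pairwise sums behind a switching
  function — rough binding-affinity rankings, not free energies.
* Site discovery operationalizes "the ligand stays put" as a Jaccard
  persistence rule on contacted-residue sets; weakly contacting ligands
  near the 0.5 thresholds can drop in and out of site-forming status.
* A single beta-sheet layer only; double-layer stacks and inter-layer
  interfaces are not modeled.
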