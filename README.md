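# oligotraj

Trajectory analysis of beta-sheet-rich peptide oligomers and their
destabilization by small-molecule ligands, in R.

Amyloidogenic peptides such as human islet amyloid polypeptide (hIAPP,
amylin, 37 residues) assemble into cross-beta oligomers: each chain folds
as beta-strand (1–17) – turn (18–27) – beta-strand (28–37) and chains
stack in register ~4.8 Å apart, zipped by inter-chain backbone hydrogen
bonds. Judging whether a simulated oligomer stays ordered, where its beta
structure is lost, and where a polyphenol-like ligand binds takes a
standard battery of trajectory statistics. `oligotraj` provides that
battery for multi-model PDB trajectories:

- **Order and fluctuations** — the nematic order parameter
  `P2 = (1/N) Σᵢ (3/2 (uᵢ·d)² − 1/2)` over chain end-to-end vectors
  `uᵢ`, with the director `d` taken as the principal eigenvector of the
  ordering tensor (ordered iff mean P2 > 0.5); Kabsch superposition,
  Cα RMSD, chain-averaged per-residue RMSF, radius of gyration.
- **Secondary structure** — a hydrogen-bond-ladder assignment over the
  alphabet {H, G, E, B, T, C} and beta-content accounting.
- **Interactions** — geometric H-bond detection (D···A < 3.5 Å,
  D-H-A > 150°), inter-peptide backbone H-bond series, residue-pair
  H-bond maps normalized to a unit maximum, per-bond occupancies,
  ligand–residue contact probabilities and contact numbers, pi-stacking
  classification, and switched Coulomb + Lennard-Jones interaction-energy
  traces (`ΔG`-free plugin-style group–group sums).
- **Landscapes and clusters** — 2-D free-energy surfaces
  `ΔG = −kT ln(P/Pmax)` over (beta content, Rg) with basin detection, and
  seeded k-medoids conformational clustering on the pairwise RMSD matrix
  with occupancies and medoid representatives.
- **Study pipeline** — binding-site discovery from contact persistence,
  site ranking by mean interaction energy, and a one-call report bundle
  (`run_full_report()`).
- **Synthetic generator** — idealized U-bend cross-beta oligomers with
  tunable orientational disorder, beta-ladder breakage, terminal fraying
  and rigid surface ligands, providing exact ground truth for every
  statistic above.

## Worked example

```r
library(oligotraj)

base <- build_ordered_oligomer(oligomer_spec(n_chains = 5))
ord <- generate_trajectory(base, disorder_spec(orientation_sigma = 5,
                                               seed = 1), n_frames = 50)
dis <- generate_trajectory(base,
                           disorder_spec(orientation_sigma = 120,
                                         ladder_break_fraction = 0.4,
                                         fray_terminal = 3, seed = 2),
                           n_frames = 50)

classify_order(p2_series(ord)$p2)
#> $label: "ordered"     $mean: 0.9937003   $sd: 0.005233558
classify_order(p2_series(dis)$p2)
#> $label: "disordered"  $mean: 0.4090232   $sd: 0.1624394
```

The ordered run keeps P2 near 1 (all chain end-to-end vectors aligned
with the director); strong per-chain orientational disorder drives the
mean below the 0.5 cutoff. Beta content and the hydrogen-bond network
degrade with it:

```r
b_ord <- beta_content(assign_ss_trajectory(ord))
b_dis <- beta_content(assign_ss_trajectory(dis))
#> beta content: 0.488 +/- 0.126 (ordered) vs 0.022 +/- 0.018 (disordered)
mean(backbone_hbond_count_series(ord)$hbonds)
#> [1] 60.32   # inter-chain backbone H-bonds per frame (108 in the template)
```

A rigid ligand anchored at residue 26 of chain B stays in persistent
surface contact and is recovered as a binding site, with its contacting
residues and mean interaction energy:

```r
cplx <- place_ligands(ord, ligand_placement(
  site = list(list(chain = "B", residue = 26))), seed = 3)
sites <- discover_sites(cplx)
#> 1 site; anchors A:25 A:26 B:25 B:26 B:27; E = -1.59 kcal/mol
```

`run_full_report(run_config(traj, out_dir = "report"))` runs the whole
study — convergence panel, order panel, secondary structure, FEL,
H-bond maps for adjacent chain pairs, clustering, site discovery — and
writes fixed-name CSV/JSON outputs that are byte-identical across reruns
with the same seed.

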