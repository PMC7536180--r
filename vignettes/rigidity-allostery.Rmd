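---
title: "Rigidity, allostery and the constraint-network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity, allostery and the constraint-network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidnet)
```

## The model

`rigidnet` treats a protein as a *body-bar framework*: every atom is a
rigid body with 6 degrees of freedom (DOF), and interactions are bars
that each remove one relative DOF. The bar counts follow the standard
molecular convention: a rotatable covalent bond contributes 5 bars
(leaving one torsion), a locked bond — peptide bonds, double and
partial-double bonds, and bonds to single-neighbor atoms — contributes
6, a hydrogen bond 5, and a hydrophobic tether 2. For generic
placements the molecular framework theorem lets a purely combinatorial
algorithm, the (6,6) pebble game, count independent constraints
exactly: each body holds 6 pebbles, a bar is independent iff 7 pebbles
can be gathered on its endpoints, and the surviving free pebbles are
the conformational DOF (6 per connected component are trivial rigid
motions). Two bodies belong to the same *rigid cluster* iff a probe bar
between them would be redundant; the decomposition, the largest rigid
cluster (LRC) and the redundant-bar count fall out of the same game.

Hydrogen bonds are ranked by the Mayo energy
$E = V_0\,[5 (d_0/d)^{12} - 6 (d_0/d)^{10}]\,F(\theta,\varphi,\gamma)$
with $V_0 = 8$ kcal/mol and $d_0 = 2.8$ Å ($d$ = donor–acceptor
distance), with the Dahiyat–Gordon–Mayo angular factor selected by
donor/acceptor hybridization. Geometric gates: $d \le 3.6$ Å and
$\theta > 90°$ strictly. A bond is *retained* at cutoff $c$ iff
$E \le c$ — more negative means stronger, and weaker bonds are ignored,
which is what a *dilution series* sweeps (default grid 0 to −2.0
kcal/mol in steps of 0.01). Salt bridges get a fixed −10 kcal/mol, so
they survive every cutoff on the default grid; both values are
arguments, not constants.

**Rigidity-transmission allostery (RTA).** Perturbing a site means
inserting bars until it is internally rigid (the implementation pins
every site body to the first one with up to 6 bars each; the game
discards the redundant ones, so only the site's genuine internal DOF
are consumed). Transmission to a target site B is the drop in the
number of pebbles gatherable on B beyond its 6 trivial ones. The scan
slides a 3-residue window from the N-terminus, and each residue's
intensity averages the (up to 3) windows containing it; windows
touching the target are excluded. Because the contract describes the
aggregation over the cutoff grid only qualitatively (DOF count and
persistence), we take the *mean transmitted DOF over the grid* as the
intensity and report *persistence* (fraction of the grid with nonzero
transmission) as a separate column rather than folding the two into an
opaque score.

**Hotspots.** "Intensity at or above the 90th percentile of nonzero
intensities" alone would label every residue of a flat profile a
hotspot; the rule therefore also requires the intensity to strictly
exceed the smallest nonzero intensity, which keeps flat profiles empty
while calling isolated peaks exactly.

**Elastic network models.** GNM uses a unit-spring Kirchhoff matrix on
Cα nodes (cutoff 7.3 Å), ANM the standard 3N Hessian (cutoff 15 Å) —
the common defaults, configurable because published server runs rarely
pin them down. "Global mode k" numbers the modes after the trivial zero
modes (1 per component for GNM, 6 for a connected ANM). Frequency
dispersion is $1/\lambda$; collectivity is the exponential-entropy
measure on normalized per-residue squared amplitudes, which is 1 for a
uniform mode and $1/N$ for a single-node mode. Domain splitting assigns
nodes by eigenvector sign; hinges are the residues flanking each sign
change, with $|u_i| < 10^{-3}$ reported as the hinge band.

**Transition-zone geometry.** Ensembles are analyzed residue-by-frame:
φ/ψ, the bond angles around the peptide unit and the O⁻¹⋯C distance,
skipping residues without two neighbors on both sides. The high-energy
zone is the *open* interval (−35°, +35°) — the source material prints
both open and closed forms; the difference cannot matter for
continuous data and the open form is adopted. Distortion fits are
ordinary least squares: quadratic in φ for the distance, and the
fixed-period single-amplitude cosine $y = I\cos(\varphi\pi/120)$ for
angle distortions measured against Engh–Huber-style reference values.

**Mutations.** Side chains are rebuilt from ideal internal coordinates
using a coarse built-in rotamer set (≤ 9 per residue type), choosing
the rotamer with the fewest heavy-atom contacts under 2.5 Å outside
the mutated residue (ties keep list order; if nothing is clash-free the
least-clashing rotamer is used with a warning). No force-field
minimization follows — that is a deliberate fidelity limit: the diff
report (LRC change, split clusters, lost/gained H-bonds, transmission
deltas at −1.0 kcal/mol) measures the *topological* consequence of the
substitution, not a relaxed structure.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| H-bond cutoff (analysis) | −0.5 | kcal/mol | dilution-plot supported choice for cluster analysis |
| H-bond cutoff (mutation diffs) | −1.0 | kcal/mol | stated mutation-comparison condition |
| dilution grid | 0 → −2.0 by 0.01 | kcal/mol | standard dilution sweep |
| Mayo V0, d0 | 8, 2.8 | kcal/mol, Å | published potential constants |
| salt-bridge energy | −10 | kcal/mol | common FIRST-style default, always retained |
| hydrophobic tether gap | 0.25 | Å | FIRST-style surface-distance default |
| site radius | 3.0 | Å | ligand-neighborhood definition |
| RTA window | 3 | residues | stated scanning protocol |
| transition zone | (−35, +35) | degrees | high-energy pass region |
| GNM / ANM cutoff | 7.3 / 15 | Å | common ENM defaults |
| rotamer clash cutoff | 2.5 | Å | heavy-atom contact threshold |

## What the synthetic world does and does not establish

Every pipeline stage is exercised on generators with *planted* ground
truth: body-bar frameworks whose DOF follow the generic count
$6n - 6c - \text{(independent bars)}$, validated against a brute-force
rigidity-matrix rank oracle at random generic placements; a two-site
toy whose site A is a path of 5-bar hinges so that rigidifying A
removes exactly the planted number of DOF at B; ideal helices with an
applied axis rotation; and NeRF-built backbone ensembles realizing
planted φ trajectories exactly, with cosine angle distortions and
quadratic O⁻¹⋯C distances imposed by construction.

A green suite therefore establishes that the *algorithms* are correct:
the pebble game equals the rank oracle, transmissions equal planted
values, fits recover planted coefficients within standard errors. It
does **not** establish reproduction of any published biological number:
the GDH structures are cryo-EM deposits that must be supplied locally,
MD ensembles are emulated by ideal-geometry backbones with no sterics,
solvent or Boltzmann weighting, and the generators' default noise
(σ = 0.01 Å on distances, ~0.3° on angles) is chosen to mimic
small-amplitude thermal jitter, not a force field. The structure-mode
pipeline runs unchanged on real files, and the headline comparisons
(LRC ratios near cutoff −0.5 kcal/mol, hotspot windows, AUC with and
without the regulatory ligand) are one function call each.

## Numerical choices

- Pebble searches are depth-first with ascending-id tie-breaks, making
  the DOF count, redundancy and cluster partition deterministic and
  insertion-order invariant (tested over 100 random permutations).
- Mutual-rigidity probes only *relocate* pebbles, so cluster testing
  never perturbs the game state.
- Eigen zero modes are detected at a relative tolerance of 1e-8;
  degenerate (collinear) ANM inputs warn and report the extra
  near-zero modes rather than failing.
- The helix axis uses the curvature (second-difference) construction,
  which is exact for ideal helices; a principal-component line — the
  obvious first choice — tilts by a few tenths of a degree when the
  sampled phases are unbalanced, enough to violate the 0.1° axis
  accuracy the generators promise. `principal_axis()` remains the
  fallback for short inputs.
- Superposition uses Kabsch with the SVD determinant correction, so a
  reflection is absorbed as RMSD, never returned as an improper
  rotation; fewer than 3 pairs or collinear selections raise errors.
- Dihedrals follow the IUPAC sign convention on (−180°, 180°]; an
  exactly-trans peptide may numerically land on either side of ±180°,
  so tests compare angles modulo 360°.
- Redundancy is counted in *bars* (a redundant 6-bar chord adds 6),
  which is what the pebble game and the rank oracle both measure.
- Altlocs keep the highest occupancy (ties keep 'A'); terminal
  protonation is out of scope (deposited structures at fixed pH);
  His gains hydrogens on both ring nitrogens and both are allowed as
  acceptors — a simplification flagged here rather than hidden.
- Interface area reports the full buried area and the half-area side
  by side, since "interface area" conventions differ.

## Known limitations

- Rigid-cluster decomposition is worst-case quadratic in bodies; fine
  for peptides and the packaged fixtures, slow for a full hexamer at
  the 0.01 kcal/mol grid (coarsen the grid first, then refine around
  the cutoff of interest).
- RTA windows slide over the residue list without chain-boundary
  awareness; multi-chain scans should be run per chain.
- Ligand bond detection falls back to covalent-radius distances (no
  GTP/NADH template library), which is correct for geometry but blind
  to bond orders, so ligand-internal rings are rotatable rather than
  locked — a conservative (flexibility-overestimating) choice.
- The cosine fit has no phase term, matching its printed fixed-period
  form; systematic phase shifts in real data would bias the amplitude
  downward.
- Proline side chains cannot be built (no backbone-coupled ring
  closure); mutations *to* proline raise an error.
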