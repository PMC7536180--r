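# rigidnet

Rigidity and allostery analysis of protein structures in R.

Allosteric regulation is often pictured as a cascade of conformational
changes, but a complementary mechanical view asks a sharper question:
if one site of a protein is made rigid, how many conformational degrees
of freedom (DOF) disappear at a distant site? `rigidnet` implements that
rigidity-theoretic toolchain for structural biologists studying
allosteric enzymes — the motivating system being homohexameric glutamate
dehydrogenase (GDH), whose GTP-inhibited closed state, open state and
apo state differ in rigidity, not just in shape:

- **Constraint networks** — atoms as rigid bodies joined by bars:
  rotatable covalent bonds (5 bars), locked/partial-double bonds (6),
  hydrogen bonds (5) ranked by the Mayo potential
  `E = V0 [5 (d0/d)^12 - 6 (d0/d)^10] F(theta, phi, gamma)` with
  `V0 = 8 kcal/mol`, `d0 = 2.8 A`, and hydrophobic tethers (2).
- **The (6,6) body-bar pebble game** — exact combinatorial DOF counting,
  rigid-cluster decomposition, largest rigid cluster (LRC) tracking, and
  hydrogen-bond dilution series over an energy-cutoff grid.
- **Rigidity-transmission allostery (RTA)** — rigidify a sliding
  three-residue window and count the DOF removed at a target site
  (e.g. the 3 A neighborhood of GTP), sweep the H-bond cutoff, summarize
  per-residue intensity curves with the rectangle-plus-triangle AUC
  `sum (x_i - x_{i-1}) y_{i-1} + 1/2 (x_i - x_{i-1})(y_i - y_{i-1})`,
  and call hotspot residues.
- **Elastic network models** — GNM/ANM modes, frequency dispersion
  `1/lambda`, exponential-entropy collectivity, sign-based domain
  splitting with hinge prediction, and mode-overlap analysis.
- **Transition-zone geometry** — per-frame backbone dihedrals over
  conformational ensembles, occupancy of the high-energy zone
  `-35 < phi < +35` degrees, and the quadratic
  (`y = a phi^2 + b phi + c`, for the O(-1)...C distance) and cosine
  (`y = I cos(phi pi/120)`, for bond-angle distortion) fits.
- **In silico mutations** — rotamer-based side-chain replacement and
  wild-type vs mutant rigidity diffs (LRC change, cluster splits, lost
  and gained H-bonds, transmission deltas).
- **Synthetic generators** — body-bar frameworks, ideal helices,
  two-site allosteric toys and backbone ensembles with *known ground
  truth*, so the whole pipeline is testable offline.

## Worked example

The demo pipeline runs every stage on synthetic fixtures with planted
ground truth:

```r
library(rigidnet)
bundle <- run_pipeline(pipeline_config(out_dir = "demo", seed = 3))
```

Selected output (from `demo/`):

```
helix_rotation.json   angle 20.1 deg  (planted 20.1; core rmsd ~ 6e-15 A)
rta_summary.json      transmitted 2   (planted 2), AUC 9 over the profile
distortion_fit.json   cosine amplitude I = 5.995, R^2 = 0.995 (planted I = 6)
framework_dof.tsv     chain(7) DOF 6/6, ring(6) DOF 0/0, tree(8) DOF 7/7
```

Reading: a helix rotated 20.1 degrees about its own axis is recovered
exactly after core superposition; rigidifying the planted allosteric
site removes exactly the 2 planted DOF at the distant site; the planted
bond-angle distortion amplitude is recovered from the generated
ensemble; and the pebble game reproduces the analytic body-bar counts
(a chain of n bodies on 5-bar hinges has n-1 torsions, a generic 6-ring
is isostatic).

On real structures (local PDB/mmCIF files; `fetch` tells you where to
get them but never downloads implicitly):

```r
m   <- add_polar_hydrogens(read_structure("3jd4.pdb"))
net <- build_constraint_network(m, hbond_cutoff = -0.5)
dec <- rigid_clusters(net)                     # LRC, cluster count, DOF
ds  <- dilution_series(m, 0, -2, 0.01)         # Fig-5-style dilution
gtp <- ligand_keys(m)[1]
site <- site_definition("GTP", residues =
          select_neighborhood(m, gtp, 3.0)$residues)
prof <- rta_scan_profile(net, site, cutoffs = -0.5)
call_hotspots(prof)
```

A command-line entry point covering `fetch`, `demo`, `run`, `compare`,
`network`, `rigidity`, `rta`, `enm`, `geometry` and `mutate` is
installed at `inst/cli/rigidnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rigidnet.R", package="rigidnet"))')" demo --out demo --seed 3
```

## Documentation

See the methods vignette (`vignettes/rigidity-allostery.Rmd`) for the
model, its assumptions, parameter defaults, what the synthetic
generators do and do not emulate, and known limitations.
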