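---
title: "Receptor-surrogate affinity models and dynamic interaction profiles: methods"
author: "AffinityProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-surrogate affinity models and dynamic interaction profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in AffinityProfiler, the
assumptions behind them, the tunable parameters and their defaults, and
the choices made where the methodology leaves the design genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Binding free-energy decomposition

An affinity estimate is assembled from five components (kcal/mol):

$$\Delta G = E_{\mathrm{inter}} + E_{\mathrm{strain}} +
  \Delta G_{\mathrm{desolv}} + T\Delta S_{\mathrm{rotors}} +
  E_{\mathrm{induced\,fit}}$$

with the convention that costs are positive and favourable interaction
is negative, and

$$\mathrm{pIC50} = -\Delta G / (\ln 10 \cdot R \cdot T), \qquad
  R = 0.0019872\ \mathrm{kcal/(mol\,K)},\ T = 300\ \mathrm{K},$$

treating IC50 as a proxy for the dissociation constant, consistent with
how pIC50-labelled training data are used throughout.  One pIC50 unit is
therefore 1.373 kcal/mol at the default temperature.  The sum is
unweighted: the exact weighting used by the original desktop
implementations is not published, so the plain sum is this package's
committed reading, and the conversion is linear and monotone (any
increased cost strictly lowers predicted affinity — a property test
enforces this).

Component definitions and defaults:

* `E_strain = max(0, E_pose − E_globalmin)`; a pose below the designated
  reference raises an `afp_inconsistent_reference` warning rather than a
  negative strain.
* `ΔG_desolv = Σ_atoms σ(element) · SASA(atom)` on the reference
  conformer.  SASA is Shrake–Rupley with a deterministic golden-spiral
  point set (960 points/atom, probe 1.4 Å).  The atomic solvation
  parameters σ (kcal/(mol·Å²)) are a bundled minimal table (polar atoms
  more expensive); a generalized-Born treatment is a documented
  extension point, not implemented.
* `TΔS_rotors = n_rotors × fraction_constrained × 0.4` kcal/mol.  The
  0.4 default sits in the literature-typical 0.3–0.6 range; both factors
  are arguments.
* Pose ensembles are pre-filtered to conformers within **10 kcal/mol**
  of the lowest-energy structure (`poseFilter`), the standard
  energetic-feasibility window.

## 2. Nonbonded terms

* van der Waals: 12-6 Lennard-Jones, arithmetic-mean σ and
  geometric-mean ε combining, per-element parameters (OPLS-flavoured).
* Electrostatics: Coulomb with k = 332.06 kcal·Å/(mol·e²); dielectric
  either constant (default ε = 1) or distance-dependent (ε·r).
* Hydrogen bond: directional 10-12 well,
  `ε_hb [5(σ_hb/r)^12 − 6(σ_hb/r)^10] · cos²θ` for D–H···A angles
  ≥ 90°, else zero; defaults ε_hb = 2 kcal/mol, σ_hb = 2.9 Å.  At the
  optimum (r = σ_hb, θ = 180°) the term is exactly −ε_hb.
* Default nonbonded cutoff 12 Å, hard truncation, no switching function
  (energies are reported per residue, not integrated over a simulation).

The original scoring function is directional with polarization and
metal–ligand terms; those two terms are **not** implemented here and a
one-time log message says so.  Absolute agreement with that software's
energies is therefore not claimable — only structural and qualitative
agreement, which is what the tests assert.

**Per-residue energies deliberately exclude the H-bond term**: the MD
profiler's residue energies are defined as the sum of van der Waals and
electrostatic terms only, so the per-residue matrix rows sum exactly to
the whole-site vdW+elec energy (conservation is tested at 1e-6 relative
tolerance over 100 random synthetic cases).  `ligandProteinEnergy`
reports the H-bond contribution separately.

## 3. Structure handling

PDB reading honours MODEL/ENDMDL multi-frame files and ignores CONECT:
connectivity is always re-perceived from a covalent-radius table
(bonded iff `d ≤ r_cov(i) + r_cov(j) + 0.45 Å`, H–H never bonded; the
slack is configurable).  Partial charges are not derivable from PDB
files: they come from a sidecar CSV (`serial,charge_e`) or, as a last
resort, a one-pass electronegativity-equalisation fallback whose
provenance is recorded on the returned object.  Ligand detection — the
heuristic is not published, so this is a committed interpretation —
takes the **largest connected component of hetero atoms** after
excluding waters (HOH/WAT/TIP/…) and single-atom ions, with ties broken
toward the lowest atom serial.  The binding site is every residue with
any atom within **8 Å** (default) of any ligand atom, excluding the
ligand's own residue and (by default) waters.

Rotatable bonds: acyclic single bonds between heavy atoms that each
carry at least one further heavy neighbour; amide C–N bonds are
excluded, recognised geometrically (the carbon bears a carbonyl-length
C–O contact ≤ 1.30 Å), since no bond orders are assigned.

## 4. The receptor surrogate

The envelope is built once per training set: candidate points on each
atom's solvent-contact sphere (vdW + 1.4 Å), points inside any other
expanded sphere discarded, then greedy minimum-distance thinning to the
requested `spacing` (default 0.8 Å).  The thinning radius is 0.93 ×
spacing, calibrated so the retained areal density is ≈ 1/spacing² (the
single-sphere count matches 4πr²/spacing² within 20%, which is a test).
Construction is deterministic for a fixed input order, and enlarging
the input union never removes existing coverage.

Each family member assigns one of seven property labels to every
particle: hydrophobic, H-bond donor, H-bond acceptor, positive,
negative, neutral, void.  Scoring a pose sums, over particles, a
bundled particle-property × atom-class compatibility energy for the
nearest ligand heavy atom, weighted by a Gaussian distance response
(optimum 3.0 Å, width 1.5 Å, hard zero beyond 6 Å); void particles are
inert.  Atom classes come from charge thresholds (±0.5 e) and N/O
donor/acceptor assignment via attached hydrogens.  The table magnitudes
are scaled so that toy-ligand affinity spreads match the 3.7–8.6 pIC50
range typical of a mannoside inhibitor series; a fixed scaffold
reference energy (−8.9 kcal/mol) centres predictions in that range.

**Scenarios.**  The induced-fit (5D) and solvation (6D) dimensions are
only named, not specified, in the source methodology; this package
commits to: six induced-fit scenarios = discrete radial envelope
dilations of 0–0.5 Å in 0.1 Å steps, each with a linear penalty
(default 2 kcal/mol per Å); two solvation scenarios = buried
(no correction) vs solvent-exposed (a −0.25 × ligand-desolvation-proxy
correction, motivated by surface-exposed pockets).  Both live behind
the scenario fields of `SurrogateModel` so a different interpretation
can replace them without touching the rest.

**4D combination.**  Per-pose pseudo free energies are combined with
Boltzmann weights from the conformational energies,
`G = −RT ln Σ_i w_i e^{−G_i/RT}` (max-shifted for stability).  Exact
duplicate poses are collapsed first: a duplicated pose is the same
microstate, and double-counting it would shift the weighted
combination.  This makes the prediction invariant under pose
duplication and permutation, and a pose with diverging conformational
energy has vanishing weight — all three are property tests.

## 5. Genetic-algorithm training and validation

The genome is the label vector plus the two scenario indices.  Defaults:
population 400, tournament size 4, uniform crossover 0.8, per-gene
mutation 0.02, 300 generations with a 30-generation plateau stop,
2 elites; the returned family is the final population's top 200 members.
Fitness is `−RMSE(train) − λ(1 − q2_internal)` with λ = 0.2.  Because a
genome carries no refittable parameters, a held-out prediction with a
fixed genome equals its training prediction, so `q2_internal` is the
training-set explained variance (1 − SSE/SS_tot); reported q² values
never come from this shortcut but from `crossValidatedR2`, which
genuinely retrains per fold (default 5 folds, stratified by affinity
with seeded shuffling, SS_tot about per-fold training means).
Y-scrambling permutes training labels per round and retrains at a
reduced budget (half population, one-third generations by default).
All stochastic steps restore the global RNG state and are pure
functions of (config, seed); bitwise reproducibility is tested.

Consensus scoring reports the family mean ± population sd and attaches
flags — `unfavourable force-field score` and/or `prefers water`
(site energy above the water-reference energy; ties resolve toward
binding) — rather than altering the predicted value, because the
numerical combination of the three consensus criteria is not published.

## 6. The synthetic world

The generators state a fixed world; they are not tuned per test:

* **Toy pocket**: a ring of four-atom residues (N–H, CA, C, O) at
  radius 6.5 Å around a small polar hetero ligand (hydroxyl donor,
  amine-like N–H, carbonyl acceptor), charges chosen so that every
  pocket residue interacts attractively; heavy-atom inter-group
  distances stay ≥ 2.2 Å.  An optional `anchor` residue donates an
  N–H···O hydrogen bond to the ligand at 3.2 Å — used by the
  contact-loss and H-bond-occupancy tests (its H···A contact is
  naturally shorter than the heavy-atom clash floor).
* **Toy ligands**: subsets of 5–7 fixed scaffold sites, each site
  assigned a class from {nonpolar C, donor O–H, acceptor O}, with
  0.25 Å per-pose jitter and U(0,3) kcal/mol conformational energies.
  Restricting the class pool to three keeps the per-site unknowns
  (7 sites × 3 classes) below the 28 noiseless training observations,
  making the recovery benchmark identifiable.
* **Benchmark envelope spacing 1.5 Å** (the general default stays
  0.8 Å): at the toy-pocket scale this yields ~114 particles, a search
  space a reduced-budget GA (population 100, 100 generations) can
  traverse, mirroring the intended modelling regime rather than a
  stress test.
* Labels are `modelPredict(true_model, ·)` plus Gaussian noise in
  pIC50 space (log-normal in IC50); the split is a seeded 70/30.
* **Scripted trajectories**: Gaussian coordinate jitter per frame;
  from the event frame onward the target residue or ligand is rigidly
  displaced along +z, cleanly severing its contacts (beyond the 12 Å
  cutoff the interaction is exactly zero).

What a green test does and does not establish: the benchmark shows the
estimator recovers a *consistent* ground truth of its own functional
form (q² ≈ 0.9, predictive r² ≈ 0.85 at the fixed benchmark seed, with
Y-scrambling collapsing q² below zero).  Across other ground-truth
seeds the recovery quality varies (q² roughly 0.65–0.90 in spot
checks), and none of this certifies accuracy on real protein–ligand
data, whose pose errors, charge models and conformational strain the
toy world does not emulate.

## 7. Numerical choices and degenerate inputs

* Errors are classed conditions (`afp_format_error`, `afp_no_ligand`,
  `afp_precondition`, `afp_param_missing`, `afp_singularity`,
  `afp_selection_error`, `afp_usage`, …) so callers can branch on them.
* r = 0 in any pair term is a singularity error, not Inf.
* The factor-of-10 band is inclusive: |ΔpIC50| ≤ 1.0 counts as within.
* `strainEnergy` clamps at zero; `poseFilter` always retains the
  minimum-energy pose; ties in ligand detection break to the lowest
  serial.
* Binding-site residues are fixed from the first frame: per-frame
  redefinition would change column identity mid-series, so enlarging
  the cutoff only adds columns (tested).
* H-bond criteria (3.5 Å, 120°) are committed defaults; the source
  reports H-bond breakage without stating criteria.  The angle test is
  applied only when the donor carries a polar hydrogen.
* MD protocol constants (TIP3P box +10 Å, 0.15 M NaCl, minimization to
  1.0 kcal/(mol·Å), NPT 300 K, 24 ps relaxation) are provenance
  metadata on every profile; simulations themselves are out of scope.
* CLI config files are JSON; the run hash covers protocol settings but
  not input/output paths, so re-running an identical protocol is
  byte-identical.

## 8. Known limitations

* No polarization, metal–ligand or bonded terms; no PBC or Ewald.
* Fallback charges are a crude one-pass scheme — sidecar charges from a
  proper QM/empirical source are strongly preferred.
* Only multi-model PDB trajectories are read (DCD/XTC are extension
  points); bond orders and protonation states are never assigned.
* The published headline statistics of the original FimH application
  (q² = 0.805, predictive r² = 0.596, 23/24 within a factor of 10)
  are not reproducible here because the underlying compound structures
  are largely undisclosed; the packaged 52-row affinity table carries
  the published experimental/predicted values only, and the synthetic
  benchmark stands in for that validation regime.
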