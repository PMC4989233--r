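---
title: "Interface-driven refinement of protein-protein complex models: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-driven refinement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the refinement model and its assumptions, the parameters that matter, what
the synthetic data generator does and does not emulate, and the design
decisions taken where the design was genuinely open.

## The refinement model

Rigid-body docking produces complex models whose interfaces are
underoptimized: side chains sit in monomer-derived rotamers, small clashes
remain, and the inter-protein orientation has never been relaxed under a
detailed energy. The package's central hypothesis — the mechanism the whole
pipeline is built around — is that *repacking interfacial side chains, then
letting the backbone and inter-protein orientation respond by short
restrained dynamics*, mimics the physical process of induced fit upon
binding and is therefore an effective refinement move.

One refinement run executes, in order:

1. **Interface detection** on the input: a residue is interfacial when its
   Cα lies within 8 Å (strict) of any Cα of another chain.
2. **Restraint construction** from the input structure. Harmonic distance
   restraints `w (d_ij - d_ij^0)^2` are placed on every Cα–Cα pair and
   every backbone amide-N/carbonyl-O pair with reference distance below
   10 Å; pairs with an interfacial endpoint carry a much smaller weight so
   the interface may move. Protocol 2 adds weak harmonic position
   restraints `w ||r_i - r_i^0||^2` on every Cα. References are anchored to
   the *input* and never rebuilt mid-run: the restraints define what
   "staying near the input model" means for the whole trajectory.
3. **Initial minimization and 1.2 ps relaxation** (4-fs Langevin steps,
   300 K). Minimization alone over-compacts; the short relaxation restores
   thermal volume before sampling starts.
4. **22 repack+relax cycles.** Each cycle repacks three clusters of up to
   five interfacial residues — a cluster is a random seed residue plus its
   nearest interfacial neighbors by Cα distance — by three Metropolis steps
   each, proposing joint rotamer assignments from the library, rejecting
   proposals that fail a steric check at 70 % van der Waals radii, and
   accepting by the Metropolis criterion on the total energy at the same
   reduced radii (clashes tolerated here are relieved by the subsequent
   dynamics, which uses full radii). A 0.6-ps relaxation follows. The
   temperature holds at 300 K and descends linearly to 50 K over the last
   six cycles, a simulated-annealing schedule driving convergence into a
   nearby low-energy basin.
5. **Final minimization** and energy evaluation at full radii.

Each enabled protocol performs 16 such runs from distinct derived seeds;
the 5 lowest-energy models per protocol are reported, ranked 1–5
(protocol 1, distance restraints only) and 6–10 (protocol 2, distance +
position restraints). Selection energy includes the restraint terms by
default (`select_with_restraints`), since they are part of the optimized
objective; a flag excludes them.

For Cn homo-oligomers, the rigid transforms mapping chain 1 onto each
chain are estimated once from the input by Kabsch superposition over Cα
atoms, and symmetry is re-imposed after every MD step by mapping all
chains into chain 1's frame with the inverse transforms, averaging, and
re-applying the transforms. This projection is the simplest operator onto
the symmetric subspace and is energy-neutral in expectation for symmetric
fluctuations. It fixes the frame to the input transforms; the oligomer's
center of mass is therefore pinned by construction rather than conserved
dynamically.

## The energy function

The refinement energy is a linear combination of physics-based terms,
knowledge-based terms and the restraint terms, with one configurable
weight per term (all defaulting to 1):

* `bonded` — harmonic bonds and angles plus periodic torsions for peptide
  planarity/trans preference and side-chain planar groups. Equilibrium
  values for side-chain terms are measured from an ideal-geometry template
  build of each residue type, so ideally built structures carry zero
  bonded strain. Force constants are deliberately capped (bonds
  250 kcal mol⁻¹ Å⁻², angles 40 kcal mol⁻¹ rad⁻²) so that the 4-fs
  heavy-atom timestep is stable under Langevin friction.
* `vdw` — Lennard-Jones 12-6 in the σ-convention (minimum −ε at
  `2^(1/6) (r_i + r_j)`), 12 Å cutoff, 1-2/1-3 pairs excluded, 1-4 scaled
  by 0.5. The `vdw_scale` argument multiplies all radii and implements the
  70 % reduction used during repacking.
* `coulomb` — screened electrostatics with the distance-dependent
  dielectric ε(r) = 4r, same exclusions.
* `solv_polar`, `solv_nonpolar` — implicit-solvation surrogates driven by a
  smooth pairwise burial count `B_i = Σ_j exp(-r_ij² / 2σ²)` (σ = 3.5 Å): a
  desolvation penalty `k q_i² B_i` for buried charges, and a
  surface-area-like hydrophobic term `γ S_i exp(-B_i / b₀)`. These occupy
  the architectural slots of a generalized-Born/SASA model; any more
  faithful implicit-solvent model can be substituted behind the same term
  interface.
* `hbond` — geometric hydrogen bonds between N donors and O acceptors
  (no explicit hydrogens): a Gaussian distance well centered at 2.9 Å
  (width 0.3 Å) times an acceptor-angle factor `(1 - cos θ_C-O···N)/2`.
* `pairstat` — a pluggable pairwise residue-type/Cβ-distance statistical
  potential (0.5 Å bins to 15 Å). The shipped default table is identically
  zero: the slot exists so a fitted knowledge-based potential can be
  loaded; tests exercise it with a synthetic seeded table.
* `rama`, `rotamer` — minus-log-probability lookups for backbone (10°
  φ/ψ grids per residue class, relative to a uniform background) and side
  chains (nearest library rotamer). These are piecewise-constant lookups:
  they contribute to Monte Carlo acceptance and to model selection but
  carry **zero gradient**, so they exert no force during minimization and
  dynamics. This is a real modeling trade-off, discussed under
  *Limitations*.
* `restraint_distance`, `restraint_position` — the harmonic input
  restraints described above.

All smooth terms have analytic gradients (verified against central
differences to 10⁻⁴ relative in the test suite) implemented in C++; the
total and per-term breakdown are exposed as an `EnergyBreakdown`.

## Parameters with units and defaults

| parameter | default | unit | role |
|---|---|---|---|
| interface cutoff | 8.0 | Å Cα–Cα | interfacial residue definition |
| restraint pair cutoff | 10.0 | Å | eligibility of Cα–Cα / N–O pairs |
| `w_non`, `w_intf`, `w_pos` | 1.0, 0.1, 0.05 | kcal mol⁻¹ Å⁻² | restraint stiffness (non-interface, interface, position) |
| timestep | 4.0 | fs | Langevin integration step |
| friction | 1.0 | ps⁻¹ | Langevin coupling |
| `T_high` → `T_low` | 300 → 50 | K | annealing schedule (last 6 of 22 cycles) |
| repack radii scale | 0.7 | — | van der Waals reduction during MC |
| clash overlap factor | 0.8 | — | steric limit as fraction of summed scaled radii (strict) |
| runs / selected | 16 / 5 | per protocol | ensemble generation and selection |

The restraint weights deserve comment: their ordering (interface ≪
non-interface, position weight small) is what matters for the mechanism —
the interface must be free to move while the monomer cores are held — and
the defaults encode that ordering. All are configuration-exposed.

## The synthetic data generator

`make_reference_complex()` builds idealized α-helical chains (φ = −57°,
ψ = −47°, ideal bond geometry, side chains from canonical rotamers) with a
heptad sequence pattern (LEU-GLU-ALA-ILE-SER-LYS-ALA) that places
rotatable hydrophobics on one face, and poses two of them as an
antiparallel dimer (or n copies as a Cn ring) at the smallest separation,
on a 0.25 Å grid, at which a deterministic greedy rotamer-repair pass
yields an interface of at least 5 residues per chain with no steric
overlap at full radii. `make_decoy()` then perturbs the last chain
rigidly by a requested rotation/translation and rescrambles a requested
fraction of interfacial side chains to random library rotamers, returning
the decoy together with its exact quality metrics against the reference.

What this emulates: docking-model pathologies at a controlled magnitude —
wrong side-chain rotamers at the interface, small rigid-body displacement,
CAPRI classes from high to incorrect along a translation sweep. What it
does **not** emulate: real protein folds (the toys are single ideal
helices), sequence diversity, monomer-backbone inaccuracy (homology-model
error), size (28–48 residues vs. hundreds), or the aperiodic landscape of
globular interfaces — a helical dimer's energy surface is nearly periodic
along the helix axis, so a decoy translated along that axis sits near a
spuriously competitive registry-shifted minimum. Passing tests on these
fixtures therefore demonstrate that the machinery (energetics, sampling,
restraints, selection, symmetry, metrics) behaves as specified, not that
refinement accuracy on real docking sets is reproduced.

Problem sizes used in the shipped tests and in `scripts/acceptance.R` were
chosen as the smallest systems that exercise every mechanism: 10–14
residues per chain, and a reduced refinement schedule (8 cycles, 8 runs
per protocol) for the stochastic refinement experiments, with the full
default schedule (22 cycles, 16 runs, both protocols) exercised once
end-to-end.

## Numerical choices

* **Integrator**: BAOAB-splitting Langevin dynamics; velocities are drawn
  from Maxwell–Boltzmann at the cycle temperature at each relaxation
  start. With T = 0 and high friction the integrator is a damped descent.
  Internal units are kcal/mol, Å, amu (1 internal time unit = 48.888 fs).
* **Minimization**: L-BFGS-B on the smooth terms with analytic gradients
  (`pgtol` as the gradient tolerance). Because the statistical lookup
  terms can step discontinuously, the minimizer guards the full objective:
  if the returned point is worse in total energy than the input, the input
  is returned unchanged, making monotonicity unconditional.
* **Ties** in model selection are broken by lower run index; cluster seeds
  are drawn without replacement whenever the interface is large enough.
* **Degenerate inputs**: an empty interface makes repacking the identity
  (with a warning); a diverging run (non-finite coordinates) is retried
  once with a fresh seed and halved timestep, then dropped from selection.
* **Strictness conventions**: all distance thresholds (8 Å interface,
  10 Å restraint pairs, clash limit, CAPRI tiers) are strict inequalities.
* **Determinism**: every stochastic operation draws from a seed passed
  explicitly; per-run sub-seeds are derived from the master seed by a
  fixed integer recurrence, so ensembles are bit-reproducible and the
  session RNG state is never disturbed.

## Design decisions taken where the design was open

* *Symmetrization rule*: coordinate averaging in chain 1's frame (see
  above), chosen over re-fitting transforms each step to keep the
  symmetry group fixed and the operator idempotent.
* *Restrained pair scope*: distance restraints span intra- and
  inter-chain pairs alike; "interfacial" classifies a pair's weight, not
  its eligibility. Sequence-adjacent N–O pairs are excluded (already
  covalently constrained).
* *Cluster construction*: a random interfacial seed plus spatial nearest
  neighbors — clusters must be spatially local for joint repacking of
  coupled side chains to be meaningful.
* *Joint proposals*: each Metropolis step proposes rotamers for the whole
  cluster at once; clusters are redrawn every cycle, so residues can be
  revisited.
* *Repacking temperature*: the Metropolis temperature follows the MD
  annealing schedule — one consistent temperature for the whole cycle.
* *vdW reduction scope*: 70 % radii apply to the Monte Carlo steps only;
  relaxation runs at full radii, since its role is to relieve the
  tolerated clashes.
* *Initial relaxation temperature*: 300 K, matching the cycle plateau.
* *Heavy-atom model*: hydrogens are dropped on input; the hydrogen-bond
  term is geometric, so protonation states and proton positions (often
  unreliable in docking models) are never needed.

## Known limitations

* The zero-gradient statistical terms mean the backbone torsion
  preferences exert no mechanical force; backbone stiffness comes from
  bonds/angles/planarity torsions and hydrogen bonds only. On the
  fixtures this makes the complex somewhat floppier than a full
  molecular-mechanics treatment: refining even a native toy dimer at the
  reduced schedule drifts its ligand RMSD by ≈1 Å, which sets a noise
  floor on pose retention. Consistently, on 2 Å rigid-body decoys the
  refined median L-RMSD sits at or slightly above the input value on some
  seeds — interface contact measures (F_nat, I-RMSD) improve or hold, the
  package's core mechanism, while global pose retention is
  lever-arm-limited on elongated helical toys.
* The solvation and pair-potential slots ship with simple surrogates; the
  architecture, not their parameterization, is the point.
* The selection energy's run-to-run spread (different packings) is large
  compared with the energy differences associated with sub-Å pose changes,
  so energy ranking discriminates packing quality more than pose accuracy
  — visible in the worked example, and consistent with the method's
  contact-refiner character.
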