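---
title: "Modelling crystallographic disorder with cluster-derived restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crystallographic disorder with cluster-derived restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disorderkit)
```

## The problem

A disordered crystal structure is a spatial (or temporal) average: the
diffraction experiment superimposes two or more molecular conformations
that cannot coexist in any single unit cell. Least-squares refinement of
such models is chronically under-determined — every split site doubles
three positional and up to six displacement parameters — and the usual
remedy, hand-crafted restraints, is slow and subjective. `disorderkit`
derives those restraints from quantum-chemistry-grade geometry instead: it
treats each disorder component as a hypothetical *ordered* structure (an
**archetype**), optimizes it inside the crystal field approximated by a
cluster of symmetry-generated neighbour molecules, and converts the
optimized geometry into SHELXL restraints and constraints. The same
computations yield archetype energies that, combined with an
interconversion barrier, let one argue whether the disorder is **static**
(frozen-in domains) or **dynamic** (interconverting in the solid).

## The procedure and its assumptions

**Archetype extraction.** One archetype per disorder group: all shared
(PART 0) atoms plus that group's atoms, occupancies reset to 1. This
assumes the disorder is substitutional over whole conformations — the
crystal is locally ordered, in domains or statistically, and each domain is
well approximated by one archetype packed in the experimental cell. Atoms
on special positions are treated as fully occupied.

**Cluster construction.** The asymmetric unit is expanded by every
space-group operation and integer lattice translation; an image molecule
joins the environment when *any* of its atoms comes within the cutoff
(default 3.75 Å) of *any* ASU atom, and it always enters as a *whole*
molecule. The translation search range is derived per axis as
`ceiling((cutoff + molecular diameter) / cell height) + 1`, which
guarantees no neighbour is missed for any cell geometry without a
hard-coded range; periodic wrapping inside the input model is resolved by
walking the bond graph and placing each neighbour at its minimum-image
position. The cluster builder is cross-checked in the test suite against a
brute-force oracle that enumerates all operator × translation images over
a generous grid.

**Fixed-environment optimization.** Only the ASU is optimized; the
environment is frozen and regenerated *from the updated ASU coordinates by
symmetry* after every cycle, so the surroundings follow the optimization.
Ten repeat cycles are run by default, which in practice converges both the
geometry and the neighbour list; an optional early stop (RMS Cartesian
displacement between successive cycles < 0.01 Å) is off by default so the
standard protocol is exactly reproduced. The backend contract is
deliberately minimal — coordinates and a fixed-atom mask in, coordinates
and a total energy (Hartree) out — so an external tight-binding optimizer
(GFN2-xTB via TURBOMOLE-format coord files with `f` fixed-atom flags) and
the built-in deterministic mock are interchangeable. The mock backend is a
rigid single-point scorer: it returns the input geometry with a smooth
exponential ASU–environment overlap energy, which keeps every pipeline
stage exercised, deterministic and finite without any external binary.
The unit cell is experimental input and is never refined or optimized.

## Restraints and constraints

Every covalent bond of an archetype becomes a DFIX and every 1–3 pair a
DANG record, with the optimized distance as target and a standard
uncertainty of 0.005 by default — tight enough that the refinement behaves
almost like a rigid-body fit while still letting torsions and the centre of
mass adjust to the data. Connectivity is perceived geometrically
(Cordero 2008 covalent radii, 0.40 Å tolerance, hydrogens limited to one
bond), always on a single archetype and never across disorder parts; a
pair inside a three-membered ring is emitted as 1–2 only, so no atom pair
ever receives conflicting DFIX and DANG targets. An exclude hook lets the
user drop restraints for atoms whose computed geometry is not trusted
(e.g. amide hydrogens at a semi-empirical level).

**Hydrogen shrink.** X-ray refinement locates electron-density centroids,
not nuclei, so all X–H bond targets are shrunk by 13.5 % (factor 0.865).
The hydrogen is *repositioned* along its bond vector and all targets —
including 1–3 targets involving that hydrogen — are recomputed from the
repositioned atom. Scaling the 1–3 distances directly would change the
bond angles; recomputation keeps them invariant, which is the physically
intended correction. (Whether published workflows scaled or recomputed the
H-containing 1–3 targets is generally not documented; recomputation is this
package's choice, flagged as such.)

**Recombination and occupancies.** The optimized archetypes are assembled
into one model with one residue (RESI) per archetype, so atom labels can
repeat across archetypes without renaming. A *whole-molecule* occupancy
free variable links each archetype's atoms — for two archetypes the SHELX
codes `10·fv + 1` and `−(10·fv + 1)` (meaning fv and 1 − fv), so one
parameter carries the occupancy of everything. For n > 2 each archetype
gets its own free variable and a SUMP instruction expresses the sum-to-one
constraint, leaving n − 1 independent occupancy parameters. Where a
solvent molecule is disordered independently of the main molecule, the
occupancy links are exposed per assembly rather than coupled by default.

**Constraints for proximate atoms.** After recombination, atoms of
different archetypes that overlay within the experimental resolution must
not carry independent displacement parameters. Atom pairs are matched *by
sequence position* across archetypes (the archetypes are written in the
same order; no graph matching is attempted) and pairs closer than 0.5 Å
(user-overridable) receive EADP constraints. EXYZ positional constraints
are available but off by default — the DFIX/DANG restraints already encode
the small positional differences, and freezing them would discard real
information. SIMU similarity restraints (s.u. 0.02 by default) can replace
EADP where physically distinct ADPs are plausible; EADP remains the
recommended default as the simplest route to physically meaningful ADPs.

**Parameter bookkeeping.** Parameter counts use the standard
small-molecule convention: 9 per anisotropic atom, 4 per isotropic atom,
one overall scale factor, one per independent occupancy free variable;
each EADP group of g atoms saves (g − 1)·6 (anisotropic) or (g − 1)·1
parameters and each EXYZ group (g − 1)·3. For the two-archetype amide
fixture (10 anisotropic non-H, 14 isotropic H) this gives 148 free
parameters and 58 restraints, which the test suite checks against an
independent shortest-path pair enumerator.

## Energetic classification

All energies are normalized to one ASU content (1 Hartree =
2625.4996 kJ/mol) before comparison. The decision rules, with
R = 8.314 J mol⁻¹ K⁻¹:

* **Plausibility.** Disorder requires conformations of similar energy to be
  available during crystallization. "Similar" is operationalized as
  |ΔE| within `similarity_factor` × RT at the crystallization temperature
  (default 1 × RT at 298 K — crystals are usually grown near ambient
  conditions); beyond 3× that window the verdict is *disorder-unlikely*.
  The 3× margin is a deliberately soft cutoff: observed archetype energy
  gaps cluster around RT but are not sharply bounded, so both knobs are
  exposed.
* **Static vs dynamic.** With similar energies and a known barrier, the
  disorder is *dynamic* if the barrier can be overcome within RT at the
  temperature of interest (barrier ≤ RT), *static* otherwise; with no
  barrier supplied the verdict is *barrier-unknown*. The package never
  computes barriers — they come from the user (e.g. a DFT scan through the
  planar transition geometry of an amide).
* **Populations.** Boltzmann occupancies are computed with the
  minimum-energy shift for numerical safety; at T = 0 all mass goes to the
  minimum (ties split equally). A consistency check compares the
  experimental occupancy ranking with the inverse energy ranking;
  occupancy gaps ≤ 0.05 are exempt, since near-50/50 occupancies carry no
  ranking information at realistic computational accuracy.

One subtlety deserves a note: verbal statements of the barrier rule are
easy to invert, and published discussions are not always internally
consistent about whether a *small* barrier means frozen-in or
interconverting disorder. This package follows the physically coherent
direction — a barrier *below* the thermal window permits interconversion,
hence dynamic disorder — which is also what the propionamide-type example
(ΔE ≈ 0.6 kJ/mol, barrier ≈ 0.2 kJ/mol, dynamic at room temperature)
requires.

## The synthetic fixtures

The generator produces three deterministic templates (seeded; the same
spec always yields byte-identical SHELX output):

* `monatomic-P1` — one argon-like atom in a 10 Å cubic P1 cell; the
  simplest cluster-builder test case (its first neighbour shell appears
  only beyond 10 Å).
* `two-part-generic` — a C–O fragment in P‑1 with two (or three)
  orientations of the O atom; exercises multi-part splitting and the
  sum-to-one occupancy plan.
* `propionamide-P21/c` — CH₃CH₂C(=O)NH₂ (5 non-H + 7 H atoms) in P2₁/c
  with two hydrogen-disorder parts modelling the up/down out-of-plane
  conformers of a small amide. Idealized bond lengths (C–C 1.52, C=O 1.23,
  C–N 1.33, C–H 1.09, N–H 1.01 Å), a 5.9 × 5.7 × 9.7 Å, β = 98° cell and a
  ±0.2 Å amide-hydrogen pucker plus a methyl torsion offset between the
  conformers were chosen once as plausible small-amide values; they are
  generator inputs, not fitted quantities.

What the fixtures do *not* emulate: realistic anisotropic displacement
ellipsoids (placeholder isotropic/diagonal values are used), diffraction
intensities, heavy-element scattering, solvent disorder coupled across
assemblies, or atoms on special positions. Passing tests therefore
demonstrate the correctness of the bookkeeping, geometry, symmetry
expansion and classification logic — not agreement with any particular
experimental refinement, which additionally depends on the external
optimizer and least-squares engine.

## Numerical choices

* Operator translations are stored exactly as integer twelfths, so operator
  composition and cluster deduplication never suffer float drift; every
  standard space-group translation is a multiple of 1/12.
* Orthogonalization follows the common convention (a along x, b in the
  x–y plane); the fractional/Cartesian round trip is exact to below
  1e−10 Å.
* Coordinates are fractional internally; Cartesian values are derived on
  demand, so there is a single source of truth.
* SHELX free-variable decoding follows SHELXL-2018 semantics: code c with
  |c| ≥ 10 refers to free variable m = ⌊|c|/10⌋ with multiplier
  p = |c| − 10m; m = 1 means fixed; negative codes mean p·(1 − fv).
  (Deposited models may predate this dialect; it is the one decoded here.)
* Instruction-file output is deterministically ordered (residue, record
  kind, atom labels) so reruns produce identical bytes.
* RMSCD between archetypes is computed in the common crystal frame without
  superposition — both archetypes live in the same fixed cell, so fitting
  would hide exactly the displacement being measured.

## Problem sizes and known limitations

The shipped examples and tests run the full pipeline on the 19-site
propionamide fixture (two 12-atom archetypes, clusters of ~17 neighbour
molecules) with ten optimization cycles, which completes in a few seconds
on one CPU; these sizes are representative of small-molecule work, where
the expensive step is the external optimizer, not this package.

Out of scope by design: the least-squares refinement itself (SHELXL or
olex2.refine consume the emitted files), aspherical/multipole scattering
models, diffuse scattering and supercell statistics, automatic detection of
disorder from residual density, bond orders and protonation-state
inference, and barrier computation. Where perceived connectivity is
chemically ambiguous the user can override the bond list; the package does
not guess intent.
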