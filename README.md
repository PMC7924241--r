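# disorderkit

Tools for modelling **disordered small-molecule crystal structures** with
restraints derived from molecule-in-cluster geometry optimizations, and for
classifying disorder as **static or dynamic** from archetype energetics.

More than a fifth of deposited small-molecule crystal structures are
disordered: the diffraction experiment sees a space/time average in which a
molecule apparently adopts two (or more) conformations at once. Refining
such models by hand is slow and under-determined — doubled atomic sites mean
doubled positional and displacement parameters fitted to the same data.
`disorderkit` automates the workflow that fixes this:

1. **Split** the disordered model into *archetype structures* — hypothetical
   ordered structures, one per disorder group (PART), each completed with
   the shared atoms.
2. **Optimize** each archetype inside a cluster of whole neighbour
   molecules generated by space-group symmetry (any-atom cutoff 3.75 Å),
   with only the asymmetric unit free and the environment fixed, in ten
   repeat cycles; the backend is pluggable (external GFN2-xTB, or the
   built-in deterministic mock for offline runs). The unit cell is never
   refined.
3. **Restrain**: every bond becomes a DFIX and every 1–3 pair a DANG record
   with the optimized distance as target (s.u. 0.005), so each archetype
   keeps its computed geometry in least-squares refinement. Bond distances
   to hydrogen are shrunk by 13.5 % (factor 0.865) to map nuclear positions
   onto X-ray electron-density centroids; 1–3 targets involving H are
   recomputed from the repositioned hydrogen so angles stay fixed.
4. **Recombine** the archetypes into one refinable SHELXL model: each
   archetype gets its own residue (RESI) and a whole-molecule occupancy
   free variable (fv and 1 − fv for two archetypes), and atom pairs from
   different archetypes closer than 0.5 Å receive EADP constraints
   (optionally EXYZ or SIMU) so the model is not over-parameterized.
5. **Classify** the disorder: archetype energies per ASU must lie within
   roughly the thermal window RT = R·T (2.48 kJ/mol at 298 K) for disorder
   to be plausible at all; given similar energies, disorder is *dynamic*
   when the interconversion barrier is below RT at the temperature of
   interest and *static* otherwise. Boltzmann populations
   p_i = exp(−E_i/RT)/Σ_j exp(−E_j/RT) connect the energies to the
   experimental occupancies.

File formats: SHELX `.ins`/`.res` (read/write, including LATT/SYMM
expansion, PART/RESI scoping and FVAR occupancy codes), CIF (read,
`_atom_site_disorder_group` mapped to PART), TURBOMOLE `coord` (write, Bohr,
fixed-atom flags) and XYZ (write).

## Worked example

```r
library(disorderkit)

model <- make_fixture(fixture_spec("propionamide-P21/c"))
res <- run_pipeline(pipeline_config(structure = model, barrier = 0.2))
res$counts
#> # A tibble: 7 × 2
#>   stage                          count
#>   <chr>                          <int>
#> 1 archetypes                         2
#> 2 cluster_size_archetype_1_final    17
#> 3 cluster_size_archetype_2_final    17
#> 4 restraints                        58
#> 5 constraints                        9
#> 6 parameters_free                  148
#> 7 parameters_constrained           114

res$assessment
#> <disorder_assessment> verdict: dynamic
#>   delta E = 0.522 kJ/mol, barrier = 0.200 kJ/mol, T = 298.0 K (RT = 2.478 kJ/mol)
```

The two hydrogen-disorder archetypes of the amide each carry 11 bonds and
18 angle pairs, hence 29 DFIX/DANG restraints per archetype and 58 in the
recombined two-residue model. Free refinement of that model would fit
148 parameters (9 per anisotropic non-H atom, 4 per isotropic H, one scale
factor, one occupancy free variable); the proximity-based EADP constraints
bring that down. With a user-supplied interconversion barrier of
0.2 kJ/mol, well below RT, the disorder is classified as dynamic.

`res$shelx_file` holds the refinable model (with the `+restraints.ins`
include stub) and `res$instruction_file$instructions` the restraint file:

```
RESI 1
DFIX 1.52 0.005 C1_1 C2_1
DFIX 0.9428 0.005 C1_1 H11_1
...
EADP C1_1 C1_2
```

A thin command-line front end ships in `inst/cli/disorderkit`
(subcommands `fixture`, `split`, `cluster`, `optimize`, `restraints`,
`constraints`, `recombine`, `classify`, `run`).

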