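# pairforce

Force distribution analysis over molecular dynamics trajectories, with a
time axis: **pairforce** reruns a previously generated trajectory through
its force field and turns the internal forces into pairwise-force and
stress time series.

Coordinate-based analyses miss the low-amplitude, functionally important
mechanics of stiff molecular cores; internal forces are both fitting-free
(they are internal coordinates) and more sensitive. This package is for
structural-bioinformatics and biophysics users who want to follow how a
mechanical load or a binding event redistributes through a molecule frame
by frame — e.g. which residues carry the load while a protein is pulled
apart in a force-clamp simulation.

## What it computes

Given a topology (atoms, charges, Lennard-Jones parameters, bonded terms,
exclusions, scaled 1-4 pairs), a trajectory (multi-frame GRO or XYZ) and
two atom groups (GROMACS NDX), for every frame:

1. **Vector pairwise forces** F⃗ᵢⱼ (force on atom *i* from atom *j*,
   kJ mol⁻¹ nm⁻¹) for bonds, angles, proper and improper dihedrals, cross
   bond–bond and cross bond–angle terms, plus cutoff Lennard-Jones and
   Coulomb pairs. Many-body (3- and 4-body) potentials are decomposed
   **exactly**: for every atom of a term, the pairwise forces involving it
   sum to its analytic force, and every pair is antisymmetric
   (F⃗ᵢⱼ = −F⃗ⱼᵢ). Pairwise forces from many-body terms need not point
   along the atom–atom separation. A pair is computed only when its two
   atoms fall in different groups (pass the same group twice to analyse
   everything).
2. **Residue pairwise forces** F⃗\_{ri,rj} = Σ\_{i∈ri, j∈rj} F⃗ᵢⱼ, acting
   on the residue centers of mass.
3. **Signed scalar pairwise forces**: the vector's norm, or its projection
   onto the separation — negative when the force on *i* points toward *j*
   (attractive), positive when away (repulsive), zero when exactly
   perpendicular.
4. **Punctual stress** Sᵢ = Σⱼ |Fⱼᵢ|: the sum of absolute scalar pairwise
   forces on an atom or residue. It is expressed in units of force (no
   area is definable at a point) and pinpoints where forces accumulate.
   Per-atom/per-residue sum, average, min and max summaries are also
   available.

Everything is streamed: one frame is held in memory at a time, and each
output file gains one text block per frame, so trajectory length never
affects memory.

PME/grid electrostatics cannot be attributed to atom pairs, so
electrostatics here is plain cutoff Coulomb. The MD engine itself
(thermostats, constraints, solvent) is out of scope — any program can
produce the trajectory.

## Worked example

A butane-like 4-atom chain (two residues, bond + angle + dihedral sharing
the middle atom pair, partial charges, a scaled 1-4 pair) is bundled as a
generator:

```r
library(pairforce)
sys <- make_toy_system("CHAIN4_DIHEDRAL")
st  <- compute_frame_pairwise(sys$frame, sys$topology, group_spec(0:3, 0:3),
                              cutoff = 1.0, mode = "SUMMED")
st
#> <pf_store> SUMMED, t = 0 ps, 6 pair entries
#>   i j            fx            fy          fz
#> 1 0 1  6.960945e-13  4.784125e-13 -88.9378195
#> 2 0 2 -1.024898e-12  1.009742e-28   0.0000000
#> 3 0 3 -6.114492e+00 -1.400791e+00  -0.8082096
#> 4 1 2  6.161738e+01 -3.028839e+01   3.4791258
#> 5 1 3 -8.243401e+01 -1.421085e-14 -16.3441111
#> 6 2 3  4.509149e+01  1.893046e+01 103.3391846
```

Each row is the summed force on atom `i` from atom `j` over all shared
potentials (the start geometry has relaxed bonds and angles, so rows 0–1
and 0–2 are dominated by the dihedral and numerical zeros). Scalarizing
and summing magnitudes gives the per-atom punctual stress;
`residue_pairwise()` collapses the store to the residue level:

```r
punctual_stress(scalarize(st, sys$frame, sys$topology, mode = "NORM"), 4)
#>   id  stress
#> 1  0   6.325
#> 2  1 152.786
#> 3  2 183.074
#> 4  3 204.690
residue_pairwise(st, sys$topology)
#>   i j        fx        fy        fz
#> 1 0 1 -26.93113 -31.68918 -13.67319
```

(The pair-0–1 dihedral force is perpendicular to that pair's separation,
so it scalarizes to zero — atom 0's stress comes from its other partners.)

### Command line

The same pipeline as a shell tool (script installed with the package):

```sh
PF=$(Rscript -e 'cat(system.file("scripts", "pairforce.R", package = "pairforce"))')
Rscript $PF fixtures --kind BEAD_CHAIN_N --n-beads 8 --pull 400 \
        --temperature 300 --steps 1000 --out-prefix clamp
Rscript $PF run --topology clamp.top --trajectory clamp.gro \
        --index clamp.ndx --groups all,all --cutoff 3 \
        --itypes COULOMB --level residue --out-stress stress.out
```

The first command integrates a toy force clamp (constant ±400 kJ mol⁻¹
nm⁻¹ on the chain termini, Langevin dynamics at 300 K) and writes
topology/trajectory/index files; the second reruns the trajectory and
streams Coulomb-only per-residue punctual stress, one block per frame at
1 ps intervals. `run` also accepts `--mode summed|detailed`,
`--scalar norm|projected`, `--out-pairs/--out-scalars/--out-summary`, and
a JSON `--config` mirroring every flag (explicit flags win);
`validate` parse-checks inputs. Logs go to stderr, results only to files.

## Acceptance script

`scripts/acceptance.R` re-runs that force-clamp workflow from scratch
against the installed package — generates the seeded 8-bead trajectory,
executes the full CLI rerun with the Coulomb-only filter, and verifies
the end-to-end extension and the parseability/non-negativity of the
per-residue stress series — then writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
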