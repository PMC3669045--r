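---
title: "Pairwise force decomposition and punctual stress: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise force decomposition and punctual stress: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairforce)
```

# The model

A molecular mechanics force field writes the potential energy as a sum of
bonded terms (each depending on 2–4 atom positions) and nonbonded pair
terms. **pairforce** re-evaluates that energy over an existing trajectory
("rerun") and attributes the resulting atomic forces to *atom pairs*. The
pairwise force $\vec F_{ij}$ is the force exerted on atom $i$ by its
interaction with atom $j$; it satisfies $\vec F_{ij} = -\vec F_{ji}$ by
construction.

Supported potentials (GROMACS functional forms, units nm / ps / kJ mol⁻¹ /
e / amu):

| kind | V | parameters |
|---|---|---|
| bond | $\tfrac12 k (r - b_0)^2$ | `k`, `b0` |
| angle | $\tfrac12 k_\theta (\theta - \theta_0)^2$ | `k`, `theta0` |
| proper dihedral | $k\,(1 + \cos(n\varphi - \varphi_s))$ | `k`, `n`, `phis` |
| improper dihedral | $\tfrac12 k_\xi (\xi - \xi_0)^2$ | `k`, `xi0` |
| cross bond–bond | $k_{rr}(r_{ij}-r_1)(r_{kj}-r_2)$ | `krr`, `r1`, `r2` |
| cross bond–angle | $k_{r\theta}(r_{ik}-r_3)(r_{ij}-r_1+r_{kj}-r_2)$ | `krt`, `r1`–`r3` |
| Lennard-Jones | $4\varepsilon[(\sigma/r)^{12}-(\sigma/r)^6]$ | per-atom $\sigma,\varepsilon$ |
| Coulomb | $k_e q_i q_j / r$ | $k_e = 138.935458$ kJ mol⁻¹ nm e⁻² |

Dihedral angles use the IUPAC convention: $\varphi$ is measured between
the $(i,j,k)$ and $(j,k,l)$ planes with its sign taken from
$\vec r_{ij}\cdot(\vec r_{kj}\times\vec r_{kl})$. Lennard-Jones
parameters combine by Lorentz–Berthelot (arithmetic $\sigma$, geometric
$\varepsilon$); this is the GROMACS default combination rule, and no
result in this package depends on the choice because the toy systems set
uniform per-atom parameters. Grid electrostatics (PME) cannot be
decomposed into atom pairs at all, so electrostatics is plain cutoff
Coulomb; a reaction-field correction is likewise not attempted.

## Decomposition of 3- and 4-body forces

Two-body terms *are* pairwise forces. Many-body terms are decomposed so
that two properties hold **exactly** (to 1e-10 relative, enforced in the
test suite): antisymmetry, and *per-atom reconstruction* — for every atom
of a term, the pairwise forces involving it sum to the analytic
$-\nabla V$ contribution of that term. The concrete schemes:

* **Angle** $(i,j,k)$, $j$ central: solve
  $a\,\hat u + b\,\hat v = -\vec F_j$ in the plane of the two unit bond
  vectors $\hat u = \hat r_{ij}$, $\hat v = \hat r_{kj}$ (a 2×2 linear
  system in the $(\hat u,\hat v)$ basis; $\vec F_j$ lies in that plane
  for any angle potential). Then $\vec F_{ij} = a\hat u$,
  $\vec F_{kj} = b\hat v$, $\vec F_{ik} = \vec F_i - a\hat u$. For the
  *harmonic* angle this last pair turns out central: substituting the
  analytic gradients gives
  $\vec F_{ik} = \frac{k_\theta(\theta-\theta_0)}{\sin\theta\, r_{ij} r_{kj}}
  (\vec r_{kj}-\vec r_{ij}) \parallel \vec r_{ik}$ — an identity the test
  suite asserts rather than fights. Near-collinear angles
  ($|\sin\theta| < 10^{-6}$) fall back to the still-exact central split
  $\vec F_{ij} = \vec F_i$, $\vec F_{kj} = \vec F_k$ with a warning.
* **Dihedral** $(i,j,k,l)$ (proper and improper):
  $\vec F_{ij} = \vec F_i$, $\vec F_{lk} = \vec F_l$,
  $\vec F_{jk} = \vec F_i + \vec F_j$; the remaining pairs carry zero.
  Because $\vec F_i$ is normal to the first bond plane, dihedral pairwise
  forces are genuinely *not* aligned with the pair separation — which is
  why all pairwise forces are stored as vectors and scalarized only on
  output.
* **Cross bond–bond**: two central pairs $\vec F_{ij} = \vec F_i$,
  $\vec F_{kj} = \vec F_k$.
* **Cross bond–angle**: each gradient component is parallel to one of
  $\hat r_{ij}, \hat r_{kj}, \hat r_{ik}$ and is assigned to that pair,
  giving three central pairs.

Exactness makes the decomposition lossless: with both groups covering all
atoms and no cutoff truncation, summing $\vec F_{ij}$ over $j$ recovers
each atom's total analytic force, and the global sum vanishes to machine
precision.

## Scalarization and punctual stress

A scalar pairwise force is the vector's norm (`NORM`) or the magnitude of
its projection on the separation (`PROJECTED`), signed by the angle
between the vector on $i$ and the direction $i \to j$: within
$(-\pi/2,\pi/2)$ the force pulls the atoms together (attractive, minus);
beyond it pushes them apart (repulsive, plus); exactly perpendicular is
neither and is set to zero. "Exactly" is decided with tolerance
$|\vec v\cdot\hat d| \le 10^{-12}\,\lVert\vec v\rVert$ — floating-point
equality would be meaningless. The convention is symmetric in $i,j$, so
one scalar per unordered pair suffices.

The punctual stress $S_i = \sum_j |F_{ji}|$ is a sum of force magnitudes
(units of force — at a dimensionless point no area, hence no
pressure-like stress, is definable). Unlike the net vector force, which
averages to zero at equilibrium, $S_i$ converges to a positive value and
highlights where forces accumulate. Residue-level quantities are treated
identically to atomic ones: residue pairwise forces are member-atom sums
acting on the residue centers of mass, and residue scalars use the
center-of-mass separation as the distance vector — the only separation
consistent with where the aggregated force acts. When pairwise forces are
kept per potential type (`DETAILED`), stress and summaries are still
computed from the per-pair *summed* vectors; restricting the interaction
filter (e.g. Coulomb only, as in electrostatic stress analyses) is the
supported way to get per-type stress.

# Parameters that matter

| parameter | default | why |
|---|---|---|
| `cutoff` | 1.0 nm | the conventional short-range LJ/Coulomb cutoff; must not exceed half the smallest box length under PBC |
| `fudge_lj`, `fudge_qq` | 1 (0.5 / 0.8333 in the toy chains) | standard 1-4 scaling of force fields with third-neighbour pairs |
| `mode` | SUMMED | one vector per atom pair; DETAILED keeps per-potential vectors at higher memory/output cost |
| scalar mode | NORM | the magnitude convention; PROJECTED bounds it from below (Cauchy–Schwarz), and the two coincide for central (pure bond) forces |
| FD step `h` | 1e-6 nm | central differences: truncation error ~h², round-off ~eps/h; 1e-6 balances both at ~1e-9 relative for kJ/mol-scale energies |

# The synthetic world

The generators stand in for a solvated protein force-clamp experiment at
desk scale. `BEAD_CHAIN_N` is a zig-zag chain of coarse beads (mass
50 amu, bond $b_0$ = 0.4 nm, $k$ = 1000 kJ mol⁻¹ nm⁻², angles
$k_\theta$ = 40 kJ mol⁻¹ rad⁻² at 130°, alternating ±0.3 e charges,
$\sigma$ = 0.35 nm, $\varepsilon$ = 0.3 kJ mol⁻¹, 1-2/1-3 exclusions and
scaled 1-4 pairs), sized so bonded and electrostatic forces are
comparable and the chain is flexible at 300 K. One residue covers each
bead pair so residue aggregation is non-trivial. The force clamp applies
the same ±400 kJ mol⁻¹ nm⁻¹ constant force used in protein-unfolding
simulations, along the initial end-to-end axis (there is no solvent box
whose largest dimension could define the direction), and reports output
at 1 ps intervals.

Dynamics are BAOAB-split Langevin (velocity half-kick, half-drift,
Ornstein–Uhlenbeck velocity update, half-drift, half-kick) — chosen over
Euler–Maruyama for its superior configurational sampling at finite step.
Stability requires roughly $\Delta t < 2/\sqrt{k_{max}/m_{min}}$
(≈0.4 ps for the chain defaults); the default $\Delta t$ = 0.01 ps is far
below it, and a potential-energy watchdog (checked every 25 steps) turns
divergence into a structured error naming the step. At zero temperature
and zero pull the minimized start is a fixed point, and at 300 K the
time-averaged kinetic energy reaches $\tfrac32 N k_B T$ within the
sanity band the tests assert (20%).

What the toys deliberately do **not** emulate: explicit solvent and its
dielectric screening, constrained bonds, NpT ensembles, PME — so a green
test establishes the *mechanics of the analysis* (decomposition
exactness, conservation, aggregation identities, streaming, sign
conventions), not fidelity to any particular protein's stress pattern.

# Numerical choices and degenerate inputs

* Minimum-image convention for orthorhombic boxes only; triclinic boxes
  are rejected. A GRO box line of zeros means "no PBC".
* Zero interatomic distance in any term, and angles at exactly 0 or π,
  raise a degenerate-geometry error rather than returning NaN.
* Pair stores key by (min id, max id) with the vector expressed as the
  force on the lower id; queries flip the sign, so antisymmetry is exact
  by construction rather than to tolerance.
* Nonbonded pairs whose prefactor is identically zero (zero charge
  product or zero combined ε) are dropped, so an interaction filter over
  a system lacking that interaction yields an empty store, not zeros.
* Output numbers print as `%.6e` (~7 significant digits); the bundled
  reader round-trips to that precision. All ids in outputs are 0-based;
  NDX input is 1-based per its dialect.

# Design choices where the design was open

* The angle/dihedral decomposition schemes above satisfy the published
  contract (exactness, antisymmetry, pairs confined to the term's atoms,
  arbitrary directions permitted); the original supplementary derivation
  is not available, so the tests pin the contract, not the scheme.
* Cross terms report under the ANGLE interaction type and improper
  dihedrals under DIHEDRAL, keeping the five-value output enum closed.
* The group test (pairs only across the two groups) is applied uniformly
  to bonded and nonbonded pairs.
* The CLI config file is JSON rather than YAML (no YAML parser among the
  package's allowed dependencies); flags win over config values.
* The historical compressed output format of earlier force-distribution
  tooling is not emulated — the line-oriented block format documented in
  the README/source is this package's own dialect.

# Known limitations

* O(N²) pair search and a pure-R integrator: appropriate for toy and
  small-molecule systems, not for large solvated proteins.
* Cutoff Coulomb misstates long-range electrostatics relative to PME;
  this is inherent to pairwise attribution, not an implementation gap.
* Urey–Bradley, CMAP, tabulated and polarizable terms, constraints and
  virtual sites are unsupported; trajectories must be GRO or XYZ text.
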