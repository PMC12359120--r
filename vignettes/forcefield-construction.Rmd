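---
title: "Force-field construction with ffcraft: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field construction with ffcraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffcraft)
```

## What the package models

ffcraft assembles and refines classical force fields for small molecules. The
MM energy is the standard functional form

$$
E = \sum_{\text{bonds}} \tfrac{k_b}{2}(r - r_0)^2
  + \sum_{\text{angles}} \tfrac{k_\theta}{2}(\theta - \theta_0)^2
  + \sum_{\text{torsions}} \sum_i A_i\,[1 + \cos(p_i\phi - \phi_i)]
  + E_{\mathrm{LJ}} + E_{\mathrm{Coul}},
$$

with 12-6 Lennard-Jones and Coulomb nonbonded terms, 1-2 and 1-3 pairs
excluded and 1-4 pairs scaled by the AMBER convention (1/1.2 for Coulomb, 1/2
for LJ). Internal units are Angstrom, kJ/mol, radians and elementary charges
throughout; unit conversion happens only in the GROMACS writers (nm,
degrees). Partial charges are user inputs — a zero-charge force field is
legal and is the default of `forcefield_from_geometry()`.

Four higher-level capabilities sit on top of this energy model:

1. **Torsion refitting.** `fit_dihedral()` fits the amplitudes $A_i$ of the
   cosine series on a chosen rotation against reference scan energies, by
   linear least squares on the residual target
   $R(\phi) = E_{\mathrm{ref}}(\phi) - E_{\mathrm{MM,rest}}(\phi)$, where the
   "rest" curve has the fitted amplitudes zeroed. A free additive constant is
   always part of the basis, because the reference and MM energy zeros are
   unrelated; it is discarded after the solve. All torsion terms sharing the
   scanned central bond are tied by their $(p, \phi_0)$ label and refit
   jointly, since they ride on the same rotation. With `fit_extrema = TRUE`
   only interior extrema of the reference curve enter the fit; extrema are
   found by sign changes of finite differences on the periodic angle grid, so
   the endpoints of a full 360° scan are treated periodically. No weighting
   or amplitude regularization is applied.

2. **Seminario constants.** `seminario_parameters()` extracts harmonic bond
   and angle constants from a Cartesian Hessian at a stationary geometry: for
   a bond, $k = \sum_m \lambda_m\,|\hat u_{ab}\cdot \hat v_m|$ over the
   eigenpairs of the negated interatomic $3\times 3$ block; for an angle, the
   two terminal bonds are combined in series through the in-plane
   perpendicular unit vectors (the classic construction; the "modified"
   averaging over equivalent terms is not applied). Blocks are symmetrized
   before eigendecomposition. A caveat worth knowing: the perpendicular
   projection of a single interatomic block does not see the full
   three-center structure of an angle term, so for a Hessian generated by a
   pure harmonic-angle potential the construction recovers
   $k(1-\cos\theta)/2$ (for equal arm lengths) rather than $k$ — about 0.63 k
   at a water-like angle. This is a property of the method, not of this
   implementation; the bond constants are exact for two-center potentials.
   Negative extracted constants are clamped to zero with a warning.

3. **An interpolation-mechanics (IM) potential.** The surface is a weighted
   sum of local second-order Taylor expansions in redundant internal
   coordinates (all bonds, angles and proper dihedrals from the bond graph),
   $E(x) = \sum_k w_k(x)\, T_k(q(x))$, with dihedral displacement components
   wrapped to $(-\pi, \pi]$. Cartesian reference data $(E_k, g_k, H_k)$ are
   transformed to internals with the Wilson B-matrix:
   $g_q = (BB^\top)^{-1} B\, g_x$ and
   $H_q = B^{+\top}(H_x - \sum_m (g_q)_m\, \partial B_m/\partial x)B^{+}$,
   with $\partial B/\partial x$ by central finite differences
   ($h = 10^{-5}$ Å — simpler and more robust here than analytic second
   derivatives of the internals) and the pseudo-inverse truncated at a
   relative singular-value cutoff of $10^{-8}$.

4. **Conformers and solvation.** Exhaustive enumeration over rotatable-bond
   torsional minima with MM (+ optional generalized-Born) minimization,
   deduplication and Boltzmann weighting; high-temperature Langevin sampling
   as the combinatorial fallback; and a geometric solvation-box builder with
   counterion neutralization and Galvani-potential corrections for ionic
   solvation free energies.

## The weighting function and its parameters

Weights are functions of the best-fit (Kabsch) all-atom Cartesian RMSD $d_k$
between the query and each stored reference geometry — no mass weighting, and
hydrogens are included. Two modes exist:

* `one_part`: $v_k = d_k^{-2p}$;
* `shepard` (default): $v_k = [(d_k/r_k)^{2p} + (d_k/r_k)^{2q}]^{-1}$,

normalized to $w_k = v_k / \sum_j v_j$. The default exponents are $2p = 12$
and $2q = 2$: the high power makes the nearest expansion dominate quickly
(the surface reproduces each data point exactly), while the low power gives
smooth long-range blending. The confidence radius $r_k$ is set per point to
the distance to its nearest database neighbor (1.0 Å for a lone point) and
refreshed on every insertion, so the crossover between expansions happens at
the natural spacing of the data. Exact hits ($d < 10^{-10}$) short-circuit to
a unit weight. The weight gradient is analytic: the derivative of the aligned
RMSD with respect to the query coordinates is $(x - \tilde x_k)/(N d_k)$ by
the envelope theorem (rotation and centroids are optimal), which the
interpolation-through-data and finite-difference tests exercise directly.

## Adaptive database construction

`build_database()` follows a torsion-scan protocol: `n_seed_structures`
(default 10) seed geometries are placed equidistantly over the full 360°
rotation of the key dihedral, each relaxed on the oracle potential with the
dihedral frozen (projected gradient descent with backtracking line search,
converged at max $|g| < 0.1$ kJ/mol/Å). After each seed is added, Langevin
dynamics on the *current* IM surface samples its neighborhood, restrained to
±18° (default) of the seed angle by a flat-bottom harmonic
(500 kJ/mol/rad² outside the window). Every `check_every` steps (default 10)
the IM energy is compared with the oracle energy; a discrepancy above
`energy_threshold` (default 8.4 kJ/mol) adds the structure and resets the
no-addition clock. A sampling run ends after `no_add_window_ps` (default
7.5 ps) without additions; the build ends when all seeds are processed or
`max_points` is reached.

`confirm_database_quality()` re-runs test dynamics — one segment started from
each stored point, so the whole database region is revisited — adds every
structure whose error exceeds the threshold, and iterates until a clean pass.
The "oracle" is any callable returning energy, Cartesian gradient and Hessian;
the shipped `torsion_oracle()` (stiff harmonic bonds/angles plus a cosine
series on one dihedral) and `harmonic_oracle()` stand in for an electronic-
structure engine so the whole pipeline runs at desk scale.

The database is saved to a self-describing binary container (magic header,
format version, then the coordinate definitions, per-point records
$q, E, g, H, x, r$ and weighting metadata), named `im_database.h5` by
default; a save/load round trip is bit-identical on all numeric payloads.

## Dynamics, minimization and the solvent box

All dynamics use a BAOAB Langevin integrator (default step 0.5 fs, friction
1/ps); conformational sampling defaults to 700 K, hot enough to cross typical
torsional barriers. MM minimization is L-BFGS with the analytic gradient,
converged at max $|g| \le 0.5$ kJ/mol/Å. Conformer deduplication treats two
structures as duplicates only if both their energy difference
($\le 0.1$ kJ/mol) and their heavy-atom best-fit RMSD ($\le 0.2$ Å) are
small, keeping the lower-energy representative in a greedy ascending pass;
molecular-symmetry automorphisms are not considered, so symmetric conformers
can be overcounted — a documented limitation.

The solvation builder centers the solute in a cubic box of edge
(max axis-aligned extent + 2 × padding), default padding 1.0 nm, and inserts
randomly placed and oriented solvent templates, rejecting any candidate with
an atom within 1.8 Å (configurable) of an existing atom. The spatial index is
a uniform cell list with cell edge ≥ cutoff, so its accept/reject decisions
are provably identical to the brute-force all-pairs scan (and are tested to
be). The target count is $\lfloor \rho\,(L^3 - V_{\text{solute}})/m \rfloor$
with the solute volume from summed vdW spheres — deliberately ignoring
sphere overlap, which slightly underestimates the accessible volume for
multi-atom solutes. SPC/E and TIP3P water templates are shipped
(0.997 g/cm³ target at ambient conditions); other solvents are user
templates. Charged solutes are neutralized with Na⁺ or Cl⁻ at random
overlap-checked positions, and `galvani_correct()` applies $-q\,\phi_G$ with
$\phi_G(\mathrm{SPC/E}) = -57.7$ kJ/mol per unit charge; the registry holds
only SPC/E, since reliable values are water-model specific.

The generalized-Born OBC-II term (`gb_obc2_energy()`) uses HCT pairwise
descreening with the standard scaling constants $(\alpha, \beta, \gamma) =
(1.0, 0.8, 4.85)$, Bondi-type radii with the 0.009 nm offset, and a default
dielectric of 78.5 (resettable). The radii passed in are the GB radii
themselves, so an isolated ion reproduces the Born expression
$-(1 - 1/\varepsilon)\,k_e q^2/(2R)$ exactly with the supplied $R$.

## Structure handling conventions

Atom indices are 0-based in the API and 1-based in file formats, the CLI and
printed reports. Bond perception links atoms within 1.3 × the sum of their
covalent radii (Cordero consensus set) and refuses geometries with atoms
closer than 0.4 Å. Rotatable bonds are acyclic bonds between non-terminal
atoms; multiplicity is 3 when both ends are sp³-like and 2 when either end is
sp²-like, with hybridization inferred from the neighbor count (3 neighbors on
C/N/B → sp²; anything else, including divalent O/S, → sp³-like, since lone
pairs preserve the threefold torsional pattern). Methyl rotors are excluded
by default. `set_dihedral_in_degrees()` rotates the distal fragment rigidly
about the bond axis — the proximal side is bitwise untouched — and refuses
ring bonds, where the rotation is ill-defined.

## What the toy oracles do and do not show

The analytic oracles make every stage testable without an electronic-
structure engine: their gradient is exact and their Hessian combines the
analytic internal first derivatives with a finite-difference
$\partial B/\partial x$ tensor (consistency with finite differences of the
gradient is below $10^{-5}$ in the shared oracle test suite). They emulate
the *shape* of a relaxed torsion profile — stiff bonded terms plus a smooth
periodic torsion — but not electronic effects: no coupling between the
torsion and bond lengths, no avoided crossings, no anharmonic bond breaking.
A passing adaptive-build test therefore demonstrates that the machinery
(sampling, thresholding, transforms, weights) is correct, not that a given
molecule's true surface would be captured by the same number of points.

## Problem sizes used in the shipped tests

The tests and the acceptance script run the full protocol on a four-atom
one-torsion chain (hydrogen peroxide geometry) with 10 seeds and sampling
windows of 0.2–0.5 ps — sizes chosen so the whole suite completes quickly on
one core while still exercising every code path; the protocol's 7.5 ps
default window is the recommended production setting. Solvent-packing checks
use water boxes of up to 30 Å (≈ 900 molecules), where random insertion
reaches the target density in full.

## Known limitations

* Seminario angle constants inherit the classic construction's systematic
  deviation discussed above.
* Ring conformers are not sampled: dihedral enumeration and rotation both
  require acyclic axes.
* GAFF/UFF atom typing, RESP charges and QM engines are out of scope;
  parameters and charges are inputs, and the oracle interface replaces the
  QM reference.
* The IM potential is single-state; multi-surface coupling is not modeled.
* Random insertion cannot equilibrate a solvent box; the output is a valid
  overlap-free starting configuration, not an equilibrated liquid.
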