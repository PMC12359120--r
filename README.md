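# ffcraft

Force-field construction for small molecules, in R. The package is aimed at
molecular-modeling practitioners who need to *build* and *audit* classical
potentials rather than just run them: refitting torsion profiles against
reference scans, extracting harmonic constants from a Hessian, assembling an
interpolated potential-energy surface from local Taylor expansions, searching
conformers, and packing solvated simulation boxes — all with plain-text,
GROMACS-compatible outputs and no external engines.

## What it computes

**Cosine-series torsion refitting.** The torsion energy of a rotation is
modeled as

    V(phi) = sum_i A_i [1 + cos(p_i phi - phi_i)]

and `fit_dihedral()` determines the barrier heights `A_i` by linear least
squares of the MM curve against reference energies (all scan points, or only
the curve's extrema). Terms are added one at a time with `add_fit_term()`;
nested refits never increase the RMSE.

**Seminario force constants.** `seminario_parameters()` turns a molecular
Hessian into harmonic bond and angle constants via eigen-decomposition of the
negated interatomic 3x3 blocks, `k = sum_m lambda_m |u_ab . v_m|`.

**Interpolation mechanics (IM).** `im_database()` + `add_point()` +
`im_energy_gradient()` implement a potential of the form
`E(x) = sum_k w_k(x) T_k(q(x))`: second-order Taylor expansions in internal
coordinates, blended by Shepard weights of the Kabsch RMSD to each reference
geometry. `build_database()` grows the database adaptively along a chosen
torsion — equidistant relaxed seeds, restrained sampling dynamics, and a
point added whenever the IM energy deviates from the reference ("oracle")
potential by more than a threshold (8.4 kJ/mol default) — and
`confirm_database_quality()` iterates test dynamics until no structure
exceeds the threshold. Any callable supplying energy/gradient/Hessian can be
the oracle; analytic toy oracles are included.

**Conformers.** `generate_conformers()` enumerates all combinations of
torsional minima over detected rotatable bonds (a set of eight 2-fold and two
3-fold bonds yields 2,304 assignments), minimizes each (optionally in OBC2
generalized-Born water), deduplicates by energy and heavy-atom RMSD, and
`calculate_boltzmann_distribution()` assigns populations.
`conformational_sampling()` is the MD alternative (700 K default).

**Solvation.** `solvate()` packs a cubic box (solute extent + 2 x 1.0 nm
padding by default) with SPC/E or TIP3P water by random insertion under a
cell-list overlap check, targets the solvent density from the accessible
volume, neutralizes charged solutes with Na+/Cl- counterions, and
`galvani_correct()` applies the -q*phi_G correction for ionic solvation free
energies (phi_G = -57.7 kJ/mol per unit charge for SPC/E).

## Worked example

```r
library(ffcraft)

# butane with a geometry-derived baseline force field + soft LJ
mol <- fixture_molecule("butane")
ff  <- forcefield_from_geometry(mol, sigma = 2.5, epsilon = 0.15)

# a reference torsion profile for the central C-C bond (synthetic here;
# read_scan_file() ingests multi-frame XYZ scans with energies)
quad <- c(0, 1, 2, 3)
gen  <- data.frame(A = c(6.0, 1.5), p = c(3, 1), phi0 = c(0, pi))
scan <- synthetic_scan(quad, gen, n_points = 19, mol = mol)
ref  <- dihedral_scan(quad, scan$angles,
                      mm_scan(mol, ff, scan) +
                        torsion_energy(scan$angles * pi / 180, gen),
                      scan$geometries)

# register two cosine terms and refit their amplitudes
ff <- add_fit_term(ff, quad, periodicity = 3, phase = 0)
ff <- add_fit_term(ff, quad, periodicity = 1, phase = 180)
ff <- fit_dihedral(ff, quad, mol, ref)
attr(ff, "fit_report")$amplitudes
#> 1|3.1415926536 3|0.0000000000
#>         1.5            6.0
attr(ff, "fit_report")$rmse
#> [1] 4.527406e-15

# conformers of the refitted force field, with populations
ens <- generate_conformers(mol, ff)
ens
#> conformer ensemble (enumerated): 3 conformers, energy span 2.00 kJ/mol
round(calculate_boltzmann_distribution(ens$energies, 298.15), 3)
#> [1] 0.409 0.409 0.182
```

The fit recovers the generating amplitudes (6.0 and 1.5 kJ/mol) to machine
precision. The three butane conformers are the degenerate gauche pair —
equally populated by symmetry and favored here because the fitted 1-fold
term penalizes the anti arrangement — followed by anti at +2.0 kJ/mol.

A shell front end wrapping the same functions is installed as `ffcraft`
(`mol info`, `mol set-dihedral`, `fit-dihedral`, `conformers`, `solvate`,
`imbuild`).

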