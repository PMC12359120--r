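#' Construct a molecular-mechanics force field
#'
#' Harmonic bonds and angles, a cosine torsion series
#' \eqn{V(\phi)=\sum_i A_i [1+\cos(p_i\phi-\phi_i)]}, 12-6 Lennard-Jones and
#' Coulomb nonbonded terms with 1-2/1-3 exclusions and scaled 1-4 interactions
#' (AMBER convention: Coulomb 1/1.2, LJ 1/2). Internal units are Angstrom,
#' kJ/mol, radians and elementary charges; conversions happen only in the
#' format writers.
#'
#' @param charges per-atom partial charges (e); default all zero
#' @param sigma per-atom LJ sigma (Angstrom)
#' @param epsilon per-atom LJ epsilon (kJ/mol)
#' @param types per-atom type labels
#' @param n_atoms atom count (required when the per-atom vectors are scalars)
#' @param scale14_coulomb,scale14_lj 1-4 scale factors
#' @return an object of class `forcefield`
#' @export
forcefield <- function(n_atoms, charges = 0, sigma = 1, epsilon = 0,
                       types = NULL, scale14_coulomb = 1 / 1.2,
                       scale14_lj = 0.5) {
  n <- as.integer(n_atoms)
  chk <- function(v, name) {
    v <- rep_len(as.numeric(v), n)
    if (!all(is.finite(v))) stop(name, " must be finite")
    v
  }
  sigma <- chk(sigma, "sigma"); epsilon <- chk(epsilon, "epsilon")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  structure(list(
    n_atoms = n,
    charges = chk(charges, "charges"),
    sigma = sigma, epsilon = epsilon,
    types = if (is.null(types)) rep("X", n) else rep_len(types, n),
    bonds = data.frame(a = integer(0), b = integer(0), k = numeric(0),
                       r0 = numeric(0)),
    angles = data.frame(a = integer(0), b = integer(0), c = integer(0),
                        k = numeric(0), theta0 = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), A = numeric(0), p = integer(0),
                           phi0 = numeric(0)),
    scale14_coulomb = scale14_coulomb, scale14_lj = scale14_lj),
    class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(paste0("forcefield: %d atoms, %d bond / %d angle / %d dihedral",
                     " terms, total charge %+.3f e\n"),
              x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              sum(x$charges)))
  invisible(x)
}

#' Add a harmonic bond term
#' @param ff a `forcefield`
#' @param a,b 0-based atom indices
#' @param k force constant, kJ/mol/Angstrom^2 (V = k/2 (r - r0)^2)
#' @param r0 equilibrium length, Angstrom
#' @return the updated forcefield
#' @export
add_bond_term <- function(ff, a, b, k, r0) {
  stopifnot(a != b, a >= 0, b >= 0, a < ff$n_atoms, b < ff$n_atoms)
  ff$bonds <- rbind(ff$bonds, data.frame(a = min(a, b), b = max(a, b),
                                         k = k, r0 = r0))
  ff
}

#' Add a harmonic angle term
#' @inheritParams add_bond_term
#' @param c 0-based index of the third atom (b is the apex)
#' @param theta0 equilibrium angle, radians
#' @export
add_angle_term <- function(ff, a, b, c, k, theta0) {
  stopifnot(length(unique(c(a, b, c))) == 3L, max(a, b, c) < ff$n_atoms)
  ff$angles <- rbind(ff$angles, data.frame(a = a, b = b, c = c,
                                           k = k, theta0 = theta0))
  ff
}

#' Add a cosine torsion term
#' @inheritParams add_bond_term
#' @param quad 0-based atom quadruple (i, j, k, l)
#' @param A barrier height, kJ/mol (may be negative during fitting)
#' @param p integer periodicity >= 1
#' @param phi0 phase, radians
#' @export
add_dihedral_term <- function(ff, quad, A, p, phi0) {
  quad <- as.integer(quad)
  stopifnot(length(quad) == 4L, length(unique(quad)) == 4L,
            max(quad) < ff$n_atoms, p >= 1L)
  ff$dihedrals <- rbind(ff$dihedrals, data.frame(
    i = quad[1], j = quad[2], k = quad[3], l = quad[4],
    A = A, p = as.integer(p), phi0 = phi0))
  ff
}

#' Cosine-series torsion energy
#'
#' Evaluates \eqn{V(\phi)=\sum_i A_i [1 + \cos(p_i \phi - \phi_i)]} in kJ/mol.
#'
#' @param phi torsion angle(s), radians
#' @param terms data.frame with columns `A`, `p`, `phi0` (one row per term)
#' @return energy in kJ/mol, vectorized over `phi`
#' @export
torsion_energy <- function(phi, terms) {
  if (!NROW(terms)) return(rep(0, length(phi)))
  vapply(phi, function(f) {
    sum(terms$A * (1 + cos(terms$p * f - terms$phi0)))
  }, numeric(1))
}

# dV/dphi of the cosine series
torsion_energy_dphi <- function(phi, terms) {
  if (!NROW(terms)) return(rep(0, length(phi)))
  vapply(phi, function(f) {
    sum(-terms$A * terms$p * sin(terms$p * f - terms$phi0))
  }, numeric(1))
}

# graph distance classification for the nonbonded exclusion policy:
# returns matrix of minimal bond-path lengths capped at 4
bond_path_classes <- function(bonds, n) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1] + 1L; b <- bonds[r, 2] + 1L
      d[a, b] <- 1; d[b, a] <- 1
    }
  }
  for (step in 1:2) {          # Floyd-like expansion up to path length 3
    for (v in seq_len(n)) {
      dv <- d[, v]
      cand <- outer(dv, d[v, ], `+`)
      d <- pmin(d, cand)
    }
  }
  d
}

# Precompute and attach the nonbonded pair list (used by MD/minimizer loops so
# the graph-distance matrix is not rebuilt every energy call).
cache_pairs <- function(ff) {
  ff$pairs_cache <- NULL
  ff$pairs_cache <- nonbonded_pairs(ff)
  ff
}

# nonbonded pair list with 1-4 flags, from the force field's bond terms
nonbonded_pairs <- function(ff) {
  if (!is.null(ff$pairs_cache)) return(ff$pairs_cache)
  n <- ff$n_atoms
  if (n < 2L) {
    return(data.frame(a = integer(0), b = integer(0), scale14 = logical(0)))
  }
  bm <- as.matrix(ff$bonds[, c("a", "b"), drop = FALSE])
  d <- bond_path_classes(bm, n)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  path <- d[upper.tri(d)]
  keep <- path >= 3
  data.frame(a = idx[keep, 1] - 1L, b = idx[keep, 2] - 1L,
             scale14 = path[keep] == 3)
}

#' Evaluate MM energy components and the analytic Cartesian gradient
#'
#' @param mol a `molecule` (its coordinates are evaluated; its bond graph is
#'   checked against the bonded terms)
#' @param ff a `forcefield`
#' @param gradient if FALSE, skip the gradient for speed
#' @return list with `energy` (named components: bond, angle, dihedral, lj,
#'   coulomb, total, all kJ/mol) and `gradient` (N x 3, kJ/mol/Angstrom)
#' @export
evaluate_mm <- function(mol, ff, gradient = TRUE) {
  if (n_atoms(mol) != ff$n_atoms) stop("atom count mismatch between molecule and forcefield")
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[r, 1]; b <- mol$bonds[r, 2]
      if (!any(ff$bonds$a == min(a, b) & ff$bonds$b == max(a, b))) {
        stop(sprintf("missing bond parameter for bond %d-%d", a + 1L, b + 1L))
      }
    }
  }
  x <- mol$coordinates
  n <- nrow(x)
  g <- matrix(0, n, 3)
  e_bond <- 0
  if (nrow(ff$bonds)) for (r in seq_len(nrow(ff$bonds))) {
    tr <- ff$bonds[r, ]
    rr <- bond_length(x, tr$a, tr$b)
    e_bond <- e_bond + 0.5 * tr$k * (rr - tr$r0)^2
    if (gradient) {
      dg <- bond_length_grad(x, tr$a, tr$b) * (tr$k * (rr - tr$r0))
      g[tr$a + 1L, ] <- g[tr$a + 1L, ] + dg[1, ]
      g[tr$b + 1L, ] <- g[tr$b + 1L, ] + dg[2, ]
    }
  }
  e_angle <- 0
  if (nrow(ff$angles)) for (r in seq_len(nrow(ff$angles))) {
    tr <- ff$angles[r, ]
    th <- angle_value(x, tr$a, tr$b, tr$c)
    e_angle <- e_angle + 0.5 * tr$k * (th - tr$theta0)^2
    if (gradient) {
      dg <- angle_grad(x, tr$a, tr$b, tr$c) * (tr$k * (th - tr$theta0))
      ids <- c(tr$a, tr$b, tr$c) + 1L
      g[ids, ] <- g[ids, ] + dg
    }
  }
  e_dih <- 0
  if (nrow(ff$dihedrals)) for (r in seq_len(nrow(ff$dihedrals))) {
    tr <- ff$dihedrals[r, ]
    phi <- dihedral_value(x, tr$i, tr$j, tr$k, tr$l)
    e_dih <- e_dih + tr$A * (1 + cos(tr$p * phi - tr$phi0))
    if (gradient) {
      dVdphi <- -tr$A * tr$p * sin(tr$p * phi - tr$phi0)
      dg <- dihedral_grad(x, tr$i, tr$j, tr$k, tr$l) * dVdphi
      ids <- c(tr$i, tr$j, tr$k, tr$l) + 1L
      g[ids, ] <- g[ids, ] + dg
    }
  }
  e_lj <- 0; e_coul <- 0
  pairs <- nonbonded_pairs(ff)
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    slj <- if (pairs$scale14[r]) ff$scale14_lj else 1
    sq <- if (pairs$scale14[r]) ff$scale14_coulomb else 1
    dv <- x[b + 1L, ] - x[a + 1L, ]
    rr <- vnorm(dv)
    sig <- 0.5 * (ff$sigma[a + 1L] + ff$sigma[b + 1L])
    eps <- sqrt(ff$epsilon[a + 1L] * ff$epsilon[b + 1L])
    qq <- ff$charges[a + 1L] * ff$charges[b + 1L]
    sr6 <- (sig / rr)^6
    e_lj <- e_lj + slj * 4 * eps * (sr6^2 - sr6)
    e_coul <- e_coul + sq * .coulomb_ke * qq / rr
    if (gradient) {
      dEdr <- slj * 4 * eps * (-12 * sr6^2 + 6 * sr6) / rr -
        sq * .coulomb_ke * qq / rr^2
      u <- dv / rr
      g[a + 1L, ] <- g[a + 1L, ] - dEdr * u
      g[b + 1L, ] <- g[b + 1L, ] + dEdr * u
    }
  }
  energy <- c(bond = e_bond, angle = e_angle, dihedral = e_dih,
              lj = e_lj, coulomb = e_coul)
  energy <- c(energy, total = sum(energy))
  list(energy = energy, gradient = if (gradient) g else NULL)
}

#' Build a baseline force field from a molecule's geometry
#'
#' Harmonic bond and angle terms at the current geometry's values with uniform
#' force constants — the usual starting point before Seminario refinement or
#' torsion refitting when no tabulated parameters are supplied.
#'
#' @param mol a `molecule` with perceived bonds
#' @param k_bond,k_angle uniform force constants (kJ/mol/A^2, kJ/mol/rad^2)
#' @param charges,sigma,epsilon per-atom nonbonded parameters
#' @return a `forcefield` with bond and angle terms (no torsions)
#' @export
forcefield_from_geometry <- function(mol, k_bond = 2000, k_angle = 300,
                                     charges = 0, sigma = 1, epsilon = 0) {
  ff <- forcefield(n_atoms(mol), charges = charges, sigma = sigma,
                   epsilon = epsilon, types = mol$elements)
  x <- mol$coordinates
  if (nrow(mol$bonds)) for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds[r, 1]; b <- mol$bonds[r, 2]
    ff <- add_bond_term(ff, a, b, k_bond, bond_length(x, a, b))
  }
  ics <- suppressWarnings(build_internal_coordinates(mol))
  if (nrow(ics$angles)) for (r in seq_len(nrow(ics$angles))) {
    ff <- add_angle_term(ff, ics$angles$a[r], ics$angles$b[r], ics$angles$c[r],
                         k_angle, angle_value(x, ics$angles$a[r],
                                              ics$angles$b[r], ics$angles$c[r]))
  }
  ff
}
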