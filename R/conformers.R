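#' Enumerate dihedral-minimum assignments over rotatable bonds
#'
#' Builds the Cartesian product of each bond's torsional minima. Minima come
#' from the force field's dominant cosine term on the bond (the minima of
#' `A[1+cos(p phi - phi0)]` lie at `phi = (phi0 + (2k+1) pi) / p`); bonds with
#' no torsion term fall back to `multiplicity` equally spaced angles starting
#' from the bond's current dihedral.
#'
#' @param bonds a `rotatable_bonds` data.frame (see
#'   [detect_rotatable_bonds()])
#' @param ff optional `forcefield` supplying torsion terms
#' @param mol optional `molecule` for the fallback current angles
#' @param cap maximum number of assignments (default 1e6)
#' @return a matrix with one row per assignment and one column per bond
#'   (angles in degrees); `nrow = prod(multiplicities)`
#' @export
enumerate_assignments <- function(bonds, ff = NULL, mol = NULL, cap = 1e6) {
  if (!nrow(bonds)) {
    return(matrix(numeric(0), nrow = 1, ncol = 0))
  }
  if (any(bonds$multiplicity < 2)) stop("multiplicities must be >= 2")
  total <- prod(bonds$multiplicity)
  if (total > cap) {
    stop("assignment count ", format(total, big.mark = ","), " exceeds cap ",
         format(cap, big.mark = ","),
         "; consider MD-based conformational sampling instead")
  }
  values <- lapply(seq_len(nrow(bonds)), function(r) {
    bond_minimum_angles(bonds[r, ], ff, mol)
  })
  as.matrix(rev(expand.grid(rev(values), KEEP.OUT.ATTRS = FALSE)))
}

bond_minimum_angles <- function(bond, ff, mol) {
  m <- bond$multiplicity
  if (!is.null(ff)) {
    quad <- c(bond$i, bond$j, bond$k, bond$l)
    rows <- which(central_bond_rows(ff$dihedrals, quad) & ff$dihedrals$A != 0)
    if (length(rows)) {
      dom <- rows[which.max(abs(ff$dihedrals$A[rows]))]
      p <- ff$dihedrals$p[dom]; phi0 <- ff$dihedrals$phi0[dom]
      k <- seq_len(p) - 1L
      return(sort(wrap_angle((phi0 + (2 * k + 1) * pi) / p) * 180 / pi))
    }
  }
  base <- if (!is.null(mol)) {
    get_dihedral_in_degrees(mol, c(bond$i, bond$j, bond$k, bond$l))
  } else 180
  sort(vapply(seq_len(m) - 1L, function(k) {
    a <- base + k * 360 / m
    ((a + 180) %% 360) - 180
  }, numeric(1)))
}

#' Minimize a molecule on its MM (+ optional implicit solvent) energy
#'
#' L-BFGS minimization with the analytic MM gradient, converged when the
#' max-norm of the gradient drops below `gtol` (default 0.5 kJ/mol/Angstrom).
#'
#' @param mol a `molecule`
#' @param ff a `forcefield`
#' @param implicit_solvent `NULL` or `"OBC2"` to add the generalized-Born
#'   water term
#' @param dielectric solvent dielectric for the GB term
#' @param gtol convergence threshold on max|gradient|
#' @param max_iter iteration cap
#' @return list `(mol, energy, max_grad, converged)`
#' @export
minimize_molecule <- function(mol, ff, implicit_solvent = NULL,
                              dielectric = 78.5, gtol = 0.5, max_iter = 2000L) {
  ff <- cache_pairs(ff)
  use_gb <- !is.null(implicit_solvent)
  if (use_gb && !toupper(implicit_solvent) %in% names(implicit_solvent_models())) {
    stop("unknown implicit solvent model '", implicit_solvent, "'; available: ",
         paste(names(implicit_solvent_models()), collapse = ", "))
  }
  n <- n_atoms(mol)
  ener <- function(v) {
    m <- mol; m$coordinates <- matrix(v, n, 3)
    e <- evaluate_mm(m, ff, gradient = FALSE)$energy[["total"]]
    if (use_gb) e <- e + gb_obc2_energy(m, ff$charges, dielectric = dielectric)
    e
  }
  grad <- function(v) {
    m <- mol; m$coordinates <- matrix(v, n, 3)
    g <- evaluate_mm(m, ff)$gradient
    if (use_gb) {
      g <- g + gb_obc2_energy(m, ff$charges, dielectric = dielectric,
                              gradient = TRUE)$gradient
    }
    as.vector(g)
  }
  v <- as.vector(mol$coordinates)
  for (round in 1:8) {
    opt <- stats::optim(v, ener, grad, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 10))
    v <- opt$par
    mg <- max(abs(grad(v)))
    if (mg <= gtol) break
  }
  mol$coordinates <- matrix(v, n, 3)
  list(mol = mol, energy = ener(v), max_grad = mg, converged = mg <= gtol)
}

#' Registry of implicit solvent models
#' @return named list of available models and their default dielectric
#' @export
implicit_solvent_models <- function() list(OBC2 = list(dielectric = 78.5))

new_ensemble <- function(mols, energies, provenance) {
  ord <- order(energies)
  structure(list(molecules = mols[ord],
                 energies = energies[ord] - min(energies),
                 provenance = provenance),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer ensemble (%s): %d conformers, energy span %.2f kJ/mol\n",
              x$provenance, length(x$energies), max(x$energies)))
  invisible(x)
}

#' Generate conformers by exhaustive dihedral enumeration
#'
#' Applies every dihedral-minimum assignment, minimizes each structure on the
#' MM (+ optional OBC2) energy, drops non-convergent candidates with a
#' warning, deduplicates and sorts by energy.
#'
#' @inheritParams minimize_molecule
#' @param bonds optional precomputed `rotatable_bonds`
#' @param energy_tol,rmsd_tol deduplication tolerances (kJ/mol, Angstrom)
#' @return a `conformer_ensemble` (relative energies, ascending)
#' @export
generate_conformers <- function(mol, ff, implicit_solvent = NULL,
                                bonds = NULL, energy_tol = 0.1,
                                rmsd_tol = 0.2) {
  if (is.null(bonds)) bonds <- detect_rotatable_bonds(mol)
  assignments <- enumerate_assignments(bonds, ff, mol)
  mols <- list(); energies <- numeric(0)
  for (r in seq_len(nrow(assignments))) {
    m <- mol
    if (ncol(assignments)) for (b in seq_len(nrow(bonds))) {
      m <- set_dihedral_in_degrees(m, c(bonds$i[b], bonds$j[b], bonds$k[b],
                                        bonds$l[b]), assignments[r, b])
    }
    res <- tryCatch(minimize_molecule(m, ff, implicit_solvent),
                    error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      warning("conformer ", r, " dropped: minimization did not converge",
              call. = FALSE)
      next
    }
    mols[[length(mols) + 1L]] <- res$mol
    energies <- c(energies, res$energy)
  }
  if (!length(mols)) stop("no conformer minimization converged")
  deduplicate(new_ensemble(mols, energies, "enumerated"),
              energy_tol, rmsd_tol)
}

#' Deduplicate a conformer ensemble
#'
#' Two conformers are duplicates iff their energies differ by at most
#' `energy_tol` and their best-fit heavy-atom RMSD is at most `rmsd_tol`;
#' a greedy pass in ascending energy order keeps the lower-energy
#' representative.
#'
#' @param ensemble a `conformer_ensemble`
#' @param energy_tol kJ/mol (default 0.1)
#' @param rmsd_tol Angstrom (default 0.2)
#' @return the filtered ensemble
#' @export
deduplicate <- function(ensemble, energy_tol = 0.1, rmsd_tol = 0.2) {
  stopifnot(energy_tol > 0, rmsd_tol > 0)
  n <- length(ensemble$energies)
  if (n < 2L) return(ensemble)
  heavy <- which(ensemble$molecules[[1]]$elements != "H")
  if (!length(heavy)) heavy <- seq_along(ensemble$molecules[[1]]$elements)
  keep <- logical(n)
  for (i in seq_len(n)) {       # ascending energy order by construction
    dup <- FALSE
    for (j in which(keep)) {
      if (abs(ensemble$energies[i] - ensemble$energies[j]) > energy_tol) next
      r <- kabsch_rmsd(ensemble$molecules[[i]]$coordinates[heavy, , drop = FALSE],
                       ensemble$molecules[[j]]$coordinates[heavy, , drop = FALSE])
      if (r <= rmsd_tol) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  new_ensemble(ensemble$molecules[keep], ensemble$energies[keep],
               ensemble$provenance)
}

#' Boltzmann populations of an energy ladder
#'
#' @param energies kJ/mol (any common offset; shifted internally)
#' @param temperature K (> 0)
#' @return probability vector summing to 1
#' @export
calculate_boltzmann_distribution <- function(energies, temperature = 298.15) {
  if (!length(energies)) stop("empty energy vector")
  if (temperature <= 0) stop("temperature must be positive")
  w <- exp(-(energies - min(energies)) / (.kB * temperature))
  w / sum(w)
}

#' Conformer generation by high-temperature MD sampling
#'
#' Runs Langevin dynamics at `temperature` (default 700 K, chosen to cross
#' torsional barriers), takes `n_snapshots` equally spaced snapshots,
#' minimizes each on the MM energy, deduplicates and sorts.
#'
#' @inheritParams generate_conformers
#' @param n_snapshots number of snapshots (pre-deduplication count)
#' @param duration_ps trajectory length, ps
#' @param temperature sampling temperature, K (default 700)
#' @param dt_fs integration step, fs
#' @param seed RNG seed
#' @return a `conformer_ensemble` with provenance `"sampled"`
#' @export
conformational_sampling <- function(mol, ff, n_snapshots = 50L,
                                    duration_ps = 5, temperature = 700,
                                    dt_fs = 1.0, seed = NULL,
                                    energy_tol = 0.1, rmsd_tol = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  ff <- cache_pairs(ff)
  masses <- atomic_mass(mol$elements)
  n_steps <- ceiling(duration_ps * 1000 / dt_fs)
  every <- max(1L, floor(n_steps / n_snapshots))
  snaps <- list()
  cb <- function(step, x, energy) {
    if (length(snaps) < n_snapshots) snaps[[length(snaps) + 1L]] <<- x
    NULL
  }
  pot <- function(x) {
    m <- mol; m$coordinates <- x
    ev <- evaluate_mm(m, ff)
    list(energy = ev$energy[["total"]], gradient = ev$gradient)
  }
  langevin_dynamics(mol$coordinates, masses, pot, n_steps = n_steps,
                    dt_fs = dt_fs, temperature = temperature,
                    callback = cb, callback_every = every)
  while (length(snaps) < n_snapshots) snaps[[length(snaps) + 1L]] <- mol$coordinates
  mols <- list(); energies <- numeric(0)
  for (s in seq_along(snaps)) {
    m <- mol; m$coordinates <- snaps[[s]]
    res <- tryCatch(minimize_molecule(m, ff), error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      warning("snapshot ", s, " dropped: minimization did not converge",
              call. = FALSE)
      next
    }
    mols[[length(mols) + 1L]] <- res$mol
    energies <- c(energies, res$energy)
  }
  ens <- deduplicate(new_ensemble(mols, energies, "sampled"),
                     energy_tol, rmsd_tol)
  attr(ens, "n_snapshots") <- length(snaps)
  ens
}

#' Write a conformer ensemble as a multi-frame XYZ file
#' @param ensemble a `conformer_ensemble`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  blocks <- vapply(seq_along(ensemble$energies), function(i) {
    write_xyz_string(ensemble$molecules[[i]],
                     comment = sprintf("conformer %d E = %.6f kJ/mol", i,
                                       ensemble$energies[i]))
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}
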