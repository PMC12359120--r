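# Shared builders for the test fixtures; everything is generated in code.

# central finite-difference gradient of a scalar function of an N x 3 matrix
fd_gradient <- function(f, x, h = 1e-6) {
  g <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(nrow(x))) for (d in seq_len(ncol(x))) {
    xp <- x; xp[a, d] <- xp[a, d] + h
    xm <- x; xm[a, d] <- xm[a, d] - h
    g[a, d] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# minimal MM force field for a fixture molecule: geometry-derived harmonic
# terms plus soft LJ so conformers are distinguishable
toy_ff <- function(mol, sigma = 2.5, epsilon = 0.15, charges = 0) {
  forcefield_from_geometry(mol, charges = charges, sigma = sigma,
                           epsilon = epsilon)
}

# two-harmonic generating torsion series used across the fit tests
gen_terms <- function() data.frame(A = c(6.0, 1.5), p = c(3, 1), phi0 = c(0, pi))

hooh_oracle_terms <- function() data.frame(A = c(8, 3), p = c(1, 2),
                                           phi0 = c(0, pi / 2))

# 4-atom planar chain with an exact cis (0) or trans (180) dihedral
planar_chain <- function(trans = TRUE) {
  y4 <- if (trans) -1 else 1
  molecule(c("C", "C", "C", "C"),
           rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, y4, 0)),
           bonds = rbind(c(0, 1), c(1, 2), c(2, 3)))
}

# brute-force O(N^2) cross-molecule contact scan over a solvated system
min_cross_distance <- function(sys) {
  groups <- c(list(sys$solute$coordinates), sys$solvent_positions)
  if (nrow(sys$ions)) {
    for (i in seq_len(nrow(sys$ions))) {
      groups <- c(groups, list(matrix(unlist(sys$ions[i, c("x", "y", "z")]),
                                      1, 3)))
    }
  }
  best <- Inf
  for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
    a <- groups[[i]]; b <- groups[[j]]
    for (r in seq_len(nrow(a))) {
      best <- min(best, sqrt((b[, 1] - a[r, 1])^2 + (b[, 2] - a[r, 2])^2 +
                               (b[, 3] - a[r, 3])^2))
    }
  }
  best
}
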