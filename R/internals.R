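#' Build the redundant internal-coordinate set from the bond graph
#'
#' All bonds, all angles a-b-c whose two bonds exist, and all proper dihedrals
#' over bonded quadruples, in a deterministic index-sorted order. Dihedral
#' coordinates are flagged periodic. Angles closer than 5 degrees to linear
#' are flagged (their Wilson rows degenerate).
#'
#' @param mol a `molecule` with perceived bonds
#' @return object of class `internal_coordinates`: data.frames `bonds`,
#'   `angles`, `dihedrals` (0-based indices) plus `n_atoms`
#' @export
build_internal_coordinates <- function(mol) {
  adj <- adjacency_list(mol)
  bonds <- as.data.frame(mol$bonds)
  angles <- NULL
  for (b in seq_len(n_atoms(mol)) - 1L) {
    nb <- sort(adj[[b + 1L]])
    if (length(nb) < 2L) next
    for (ii in seq_len(length(nb) - 1L)) for (jj in (ii + 1L):length(nb)) {
      angles <- rbind(angles, data.frame(a = nb[ii], b = b, c = nb[jj]))
    }
  }
  if (is.null(angles)) angles <- data.frame(a = integer(0), b = integer(0),
                                            c = integer(0))
  dihedrals <- NULL
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    j <- bonds$a[r]; k <- bonds$b[r]
    for (i in sort(setdiff(adj[[j + 1L]], k))) {
      for (l in sort(setdiff(adj[[k + 1L]], j))) {
        if (i == l) next
        dihedrals <- rbind(dihedrals, data.frame(i = i, j = j, k = k, l = l))
      }
    }
  }
  if (is.null(dihedrals)) dihedrals <- data.frame(i = integer(0), j = integer(0),
                                                  k = integer(0), l = integer(0))
  ics <- structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                        n_atoms = n_atoms(mol)),
                   class = "internal_coordinates")
  lin <- linear_angles(ics, mol$coordinates)
  if (any(lin)) {
    warning(sum(lin), " near-linear angle(s) (> 175 deg) in the coordinate set",
            call. = FALSE)
  }
  ics
}

linear_angles <- function(ics, x) {
  if (!nrow(ics$angles)) return(logical(0))
  vapply(seq_len(nrow(ics$angles)), function(r) {
    angle_value(x, ics$angles$a[r], ics$angles$b[r], ics$angles$c[r]) >
      175 * pi / 180
  }, logical(1))
}

#' @export
print.internal_coordinates <- function(x, ...) {
  cat(sprintf("internal coordinates: %d bonds, %d angles, %d dihedrals (%d atoms)\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals), x$n_atoms))
  invisible(x)
}

n_internals <- function(ics) nrow(ics$bonds) + nrow(ics$angles) + nrow(ics$dihedrals)

# TRUE for the periodic (dihedral) components of q
periodic_mask <- function(ics) {
  c(rep(FALSE, nrow(ics$bonds) + nrow(ics$angles)),
    rep(TRUE, nrow(ics$dihedrals)))
}

#' Internal-coordinate values of a geometry
#' @param x N x 3 Cartesian coordinates, Angstrom
#' @param ics an `internal_coordinates` set
#' @return numeric vector q (Angstrom for bonds, radians for angles/dihedrals)
#' @export
internal_values <- function(x, ics) {
  qb <- if (nrow(ics$bonds)) {
    vapply(seq_len(nrow(ics$bonds)), function(r) {
      bond_length(x, ics$bonds$a[r], ics$bonds$b[r])
    }, numeric(1))
  } else numeric(0)
  qa <- if (nrow(ics$angles)) {
    vapply(seq_len(nrow(ics$angles)), function(r) {
      angle_value(x, ics$angles$a[r], ics$angles$b[r], ics$angles$c[r])
    }, numeric(1))
  } else numeric(0)
  qd <- if (nrow(ics$dihedrals)) {
    vapply(seq_len(nrow(ics$dihedrals)), function(r) {
      dihedral_value(x, ics$dihedrals$i[r], ics$dihedrals$j[r],
                     ics$dihedrals$k[r], ics$dihedrals$l[r])
    }, numeric(1))
  } else numeric(0)
  c(qb, qa, qd)
}

#' Wilson B-matrix (dq/dx) at a geometry
#' @inheritParams internal_values
#' @return M x 3N matrix, rows ordered as `internal_values`
#' @export
wilson_b <- function(x, ics) {
  M <- n_internals(ics)
  B <- matrix(0, M, 3 * nrow(x))
  row <- 0L
  put <- function(B, row, atoms, grads) {
    for (t in seq_along(atoms)) {
      cols <- (3 * atoms[t] + 1):(3 * atoms[t] + 3)
      B[row, cols] <- B[row, cols] + grads[t, ]
    }
    B
  }
  if (nrow(ics$bonds)) for (r in seq_len(nrow(ics$bonds))) {
    row <- row + 1L
    a <- ics$bonds$a[r]; b <- ics$bonds$b[r]
    B <- put(B, row, c(a, b), bond_length_grad(x, a, b))
  }
  if (nrow(ics$angles)) for (r in seq_len(nrow(ics$angles))) {
    row <- row + 1L
    a <- ics$angles$a[r]; b <- ics$angles$b[r]; c <- ics$angles$c[r]
    B <- put(B, row, c(a, b, c), angle_grad(x, a, b, c))
  }
  if (nrow(ics$dihedrals)) for (r in seq_len(nrow(ics$dihedrals))) {
    row <- row + 1L
    i <- ics$dihedrals$i[r]; j <- ics$dihedrals$j[r]
    k <- ics$dihedrals$k[r]; l <- ics$dihedrals$l[r]
    B <- put(B, row, c(i, j, k, l), dihedral_grad(x, i, j, k, l))
  }
  B
}

# right pseudo-inverse B+ = Bt (B Bt)^-1 via SVD with relative cutoff
pinv_cut <- function(A, rel_cutoff = 1e-8) {
  s <- svd(A)
  keep <- s$d > rel_cutoff * max(s$d)
  if (!any(keep)) stop("rank collapse: internal coordinate set is degenerate")
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Transform Cartesian derivatives into internal coordinates
#'
#' `g_int = (B Bt)^-1 B g_cart` and
#' `H_int = B+t (H_cart - sum_m g_int_m dB_m/dx) B+`, with the B-matrix
#' derivative tensor by central finite differences (h = 1e-5 Angstrom) and the
#' generalized inverse truncated at a relative singular-value cutoff of 1e-8.
#'
#' @param x N x 3 geometry, Angstrom
#' @param g_cart Cartesian gradient (3N or N x 3), kJ/mol/Angstrom
#' @param H_cart 3N x 3N Cartesian Hessian, kJ/mol/Angstrom^2
#' @param ics an `internal_coordinates` set
#' @return list `(q, g_int, H_int)`
#' @export
transform_derivatives <- function(x, g_cart, H_cart, ics) {
  g_cart <- as.vector(t(g_cart))
  if (length(g_cart) != 3 * nrow(x)) stop("gradient dimension mismatch")
  if (!is.matrix(H_cart) || any(dim(H_cart) != 3 * nrow(x))) {
    stop("hessian dimension mismatch")
  }
  B <- wilson_b(x, ics)
  if (qr(B)$rank < min(3 * nrow(x) - 6, n_internals(ics))) {
    stop("rank collapse: too few independent internal coordinates")
  }
  Bp <- pinv_cut(B)              # 3N x M
  g_int <- as.vector(t(Bp) %*% g_cart)
  # correction term: second derivatives of the internals
  h <- 1e-5
  corr <- matrix(0, 3 * nrow(x), 3 * nrow(x))
  for (col in seq_len(3 * nrow(x))) {
    a <- (col - 1) %/% 3 + 1; d <- (col - 1) %% 3 + 1
    xp <- x; xp[a, d] <- xp[a, d] + h
    xm <- x; xm[a, d] <- xm[a, d] - h
    dB <- (wilson_b(xp, ics) - wilson_b(xm, ics)) / (2 * h)  # M x 3N
    corr[, col] <- as.vector(t(dB) %*% g_int)
  }
  corr <- (corr + t(corr)) / 2
  H_int <- t(Bp) %*% (H_cart - corr) %*% Bp
  H_int <- (H_int + t(H_int)) / 2
  list(q = internal_values(x, ics), g_int = g_int, H_int = H_int)
}
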