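#' Register a new torsion term for fitting
#'
#' Appends a cosine term with amplitude 0 to the given quadruple, so the MM
#' curve is unchanged until the next refit. Phase is given in degrees to match
#' the usual user-facing convention.
#'
#' @param ff a `forcefield`
#' @param quad 0-based atom quadruple
#' @param periodicity integer p >= 1
#' @param phase phase in degrees
#' @return the updated forcefield
#' @export
add_fit_term <- function(ff, quad, periodicity, phase = 0) {
  quad <- as.integer(quad)
  phi0 <- phase * pi / 180
  on_quad <- quad_rows(ff$dihedrals, quad)
  dup <- on_quad & ff$dihedrals$p == as.integer(periodicity) &
    abs(wrap_angle(ff$dihedrals$phi0 - phi0)) < 1e-9
  if (any(dup)) {
    stop(sprintf("term (p=%d, phase=%g deg) already present on quad %s",
                 periodicity, phase, paste(quad + 1L, collapse = "-")))
  }
  add_dihedral_term(ff, quad, A = 0, p = periodicity, phi0 = phi0)
}

quad_rows <- function(dihedrals, quad) {
  fwd <- dihedrals$i == quad[1] & dihedrals$j == quad[2] &
    dihedrals$k == quad[3] & dihedrals$l == quad[4]
  rev <- dihedrals$i == quad[4] & dihedrals$j == quad[3] &
    dihedrals$k == quad[2] & dihedrals$l == quad[1]
  fwd | rev
}

# rows whose central bond matches quad's central bond (either orientation);
# equivalent quads sharing the rotation are refit jointly with tied amplitudes
central_bond_rows <- function(dihedrals, quad) {
  (dihedrals$j == quad[2] & dihedrals$k == quad[3]) |
    (dihedrals$j == quad[3] & dihedrals$k == quad[2])
}

#' Least-squares refit of torsion amplitudes against a reference scan
#'
#' Fits the amplitudes of every cosine term on the scanned rotation (all
#' torsion terms sharing the central bond are tied by (p, phase) group and
#' refit jointly) so the MM curve matches the reference energies. The target
#' is the residual `E_ref - E_MM,rest` where `E_MM,rest` is the MM curve with
#' the fitted amplitudes zeroed; a free additive constant absorbs the
#' arbitrary energy zeros and is discarded. With `fit_extrema`, only interior
#' extrema of the reference curve (detected by discrete sign changes on the
#' periodic grid) enter the fit.
#'
#' @param ff a `forcefield` with at least one torsion term on the quad
#' @param quad the scanned 0-based quadruple
#' @param mol the `molecule` (used for rigid-rotation frames and for
#'   measuring equivalent dihedrals on stored geometries)
#' @param scan a `dihedral_scan`
#' @param fit_extrema fit only the extrema of the reference curve
#' @return the refitted forcefield, with a `fit_report` attribute: a list with
#'   `rmse`, `max_dev`, `rmse_before`, `n_points`, `amplitudes`
#' @export
fit_dihedral <- function(ff, quad, mol, scan, fit_extrema = FALSE) {
  quad <- as.integer(quad)
  rows <- which(central_bond_rows(ff$dihedrals, quad))
  if (!length(rows)) {
    stop("no torsion term registered on the rotation of quad ",
         paste(quad + 1L, collapse = "-"), "; use add_fit_term() first")
  }
  # tie amplitudes by (p, phi0) group across equivalent quads
  key <- sprintf("%d|%.10f", ff$dihedrals$p[rows],
                 wrap_angle(ff$dihedrals$phi0[rows]))
  groups <- split(rows, key)
  sel <- seq_along(scan$angles)
  if (fit_extrema) {
    sel <- which(periodic_extrema(scan$angles, scan$energies))
    if (length(sel) < 2L) stop("fit_extrema: fewer than two extrema detected")
  }
  if (length(sel) < length(groups) + 1L) {
    stop(sprintf("fit is underdetermined: %d points for %d amplitudes + offset",
                 length(sel), length(groups)))
  }

  ff_rest <- ff
  ff_rest$dihedrals$A[rows] <- 0
  ff_rest <- cache_pairs(ff_rest)
  n_sel <- length(sel)
  basis <- matrix(0, n_sel, length(groups))
  e_rest <- numeric(n_sel)
  e_now <- numeric(n_sel)
  ff_c <- cache_pairs(ff)
  for (s in seq_len(n_sel)) {
    m <- scan_frame_molecule(mol, scan, sel[s])
    e_rest[s] <- evaluate_mm(m, ff_rest, gradient = FALSE)$energy[["total"]]
    e_now[s] <- evaluate_mm(m, ff_c, gradient = FALSE)$energy[["total"]]
    for (gi in seq_along(groups)) {
      for (r in groups[[gi]]) {
        tr <- ff$dihedrals[r, ]
        phi <- dihedral_value(m$coordinates, tr$i, tr$j, tr$k, tr$l)
        basis[s, gi] <- basis[s, gi] + 1 + cos(tr$p * phi - tr$phi0)
      }
    }
  }
  X <- cbind(basis, offset = 1)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient torsion basis: duplicate (p, phase) terms on the scan")
  }
  y <- scan$energies[sel] - e_rest
  beta <- qr.solve(X, y)
  amps <- beta[seq_along(groups)]
  for (gi in seq_along(groups)) ff$dihedrals$A[groups[[gi]]] <- amps[gi]

  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  resid_before <- scan$energies[sel] - e_now -
    mean(scan$energies[sel] - e_now)
  attr(ff, "fit_report") <- list(
    rmse = sqrt(mean(resid^2)),
    max_dev = max(abs(resid)),
    rmse_before = sqrt(mean(resid_before^2)),
    n_points = n_sel,
    amplitudes = stats::setNames(amps, names(groups)))
  ff
}

# interior extrema of a periodic curve: discrete sign change of the forward
# finite differences on the angle-sorted periodic grid
periodic_extrema <- function(angles, energies) {
  ord <- order(angles)
  e <- energies[ord]
  n <- length(e)
  dfwd <- e[c(2:n, 1)] - e            # difference to the next point (periodic)
  dbwd <- e - e[c(n, 1:(n - 1))]      # difference from the previous point
  ext_sorted <- sign(dfwd) * sign(dbwd) < 0 | dfwd == 0 | dbwd == 0
  ext <- logical(n)
  ext[ord] <- ext_sorted
  ext
}
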