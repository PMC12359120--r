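#' Seminario bond and angle force constants from a Cartesian Hessian
#'
#' Extracts harmonic force constants from the eigen-decomposition of the
#' negated 3x3 interatomic blocks of a molecular Hessian evaluated at a
#' stationary geometry. For a bond a-b,
#' \eqn{k_{ab} = \sum_m \lambda_m |\hat u_{ab} \cdot \hat v_m|} over the
#' eigenpairs of \eqn{-H[a,b]}; angle constants combine the two terminal bonds
#' through the in-plane perpendicular unit vectors (the classic construction,
#' without the "modified Seminario" averaging). Equilibrium values r0 and
#' theta0 are taken from the input geometry.
#'
#' @param mol a `molecule` with perceived bonds (defines which bond/angle
#'   constants are extracted)
#' @param hessian 3N x 3N symmetric Cartesian Hessian, kJ/mol/Angstrom^2,
#'   atom-major ordering (rows 3a+1..3a+3 belong to atom a+1)
#' @return list with data.frames `bonds` (a, b, k, r0) and
#'   `angles` (a, b, c, k, theta0); k in kJ/mol/Angstrom^2 and kJ/mol/rad^2
#' @export
seminario_parameters <- function(mol, hessian) {
  n <- n_atoms(mol)
  if (!is.matrix(hessian) || any(dim(hessian) != 3 * n)) {
    stop("hessian must be a 3N x 3N matrix")
  }
  if (max(abs(hessian - t(hessian))) > 1e-6 * max(1, max(abs(hessian)))) {
    stop("hessian is not symmetric")
  }
  x <- mol$coordinates
  block <- function(a, b) {
    -hessian[(3 * a + 1):(3 * a + 3), (3 * b + 1):(3 * b + 3)]
  }
  # sum_m lambda_m |u . v_m| for the eigenpairs of the (symmetrized) block
  proj_sum <- function(K, u) {
    K <- (K + t(K)) / 2
    e <- eigen(K, symmetric = TRUE)
    sum(e$values * abs(as.vector(u %*% e$vectors)))
  }
  clamp0 <- function(k, label) {
    if (k < 0) {
      warning("negative Seminario force constant for ", label,
              "; clamped to 0", call. = FALSE)
      0
    } else k
  }

  bonds <- NULL
  if (nrow(mol$bonds)) for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds[r, 1]; b <- mol$bonds[r, 2]
    u <- x[b + 1L, ] - x[a + 1L, ]; u <- u / vnorm(u)
    k <- clamp0(proj_sum(block(a, b), u), paste0("bond ", a + 1L, "-", b + 1L))
    bonds <- rbind(bonds, data.frame(a = a, b = b, k = k,
                                     r0 = bond_length(x, a, b)))
  }
  if (is.null(bonds)) {
    bonds <- data.frame(a = integer(0), b = integer(0), k = numeric(0),
                        r0 = numeric(0))
  }

  adj <- adjacency_list(mol)
  angles <- NULL
  for (b in seq_len(n) - 1L) {
    nb <- sort(adj[[b + 1L]])
    if (length(nb) < 2L) next
    for (ii in seq_len(length(nb) - 1L)) for (jj in (ii + 1L):length(nb)) {
      a <- nb[ii]; c <- nb[jj]
      u_ab <- x[a + 1L, ] - x[b + 1L, ]
      u_cb <- x[c + 1L, ] - x[b + 1L, ]
      R_ab <- vnorm(u_ab); R_cb <- vnorm(u_cb)
      u_ab <- u_ab / R_ab; u_cb <- u_cb / R_cb
      u_n <- vcross(u_cb, u_ab)
      if (vnorm(u_n) < 1e-8) next   # near-linear angle: construction degenerate
      u_n <- u_n / vnorm(u_n)
      u_pa <- vcross(u_n, u_ab)
      u_pc <- vcross(u_cb, u_n)
      den_a <- R_ab^2 * proj_sum(block(a, b), u_pa)
      den_c <- R_cb^2 * proj_sum(block(c, b), u_pc)
      k <- if (den_a <= 0 || den_c <= 0) 0 else 1 / (1 / den_a + 1 / den_c)
      k <- clamp0(k, paste(a + 1L, b + 1L, c + 1L, sep = "-"))
      angles <- rbind(angles, data.frame(a = a, b = b, c = c, k = k,
                                         theta0 = angle_value(x, a, b, c)))
    }
  }
  if (is.null(angles)) {
    angles <- data.frame(a = integer(0), b = integer(0), c = integer(0),
                         k = numeric(0), theta0 = numeric(0))
  }
  list(bonds = bonds, angles = angles)
}
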