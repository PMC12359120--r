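# Analytic oracle potentials implementing the x -> (E, gradient, hessian)
# contract that the interpolation module consumes, plus small fixture
# molecules and synthetic torsion scans. These stand in for an electronic-
# structure engine so every stage runs at desk scale.

#' Harmonic (globally quadratic) oracle potential
#'
#' `E = (x - x0)' H0 (x - x0) / 2` with constant Hessian `H0`.
#'
#' @param x0 N x 3 reference geometry
#' @param H0 3N x 3N symmetric PSD matrix (atom-major ordering)
#' @return callable `x -> list(energy, gradient, hessian)`; the callable
#'   accepts an optional second argument `need` (`"all"`, `"gradient"` or
#'   `"energy"`) to skip the unneeded derivatives
#' @export
harmonic_oracle <- function(x0, H0) {
  if (max(abs(H0 - t(H0))) > 1e-10 * max(1, max(abs(H0)))) {
    stop("H0 must be symmetric")
  }
  v0 <- as.vector(t(x0))
  n <- nrow(x0)
  function(x, need = "all") {
    dv <- as.vector(t(x)) - v0
    g <- as.vector(H0 %*% dv)
    out <- list(energy = 0.5 * sum(dv * g))
    if (need != "energy") out$gradient <- matrix(g, n, 3, byrow = TRUE)
    if (need == "all") out$hessian <- H0
    out
  }
}

#' Torsional oracle potential
#'
#' Stiff harmonic bonds and angles (taken at the template's geometry) plus a
#' cosine torsion series on one dihedral:
#' `E = sum k_b/2 (r-r0)^2 + sum k_a/2 (th-th0)^2 + sum A_i [1+cos(p_i phi - phi_i)]`.
#' Gradient is analytic; the Hessian uses the analytic internal first
#' derivatives with the second-derivative tensor of the internals obtained by
#' central differences of the Wilson rows.
#'
#' @param mol template `molecule` with perceived bonds (equilibrium geometry)
#' @param quad 0-based quadruple carrying the torsion series
#' @param terms data.frame with columns `A`, `p`, `phi0` (kJ/mol, -, radians)
#' @param k_bond,k_angle harmonic constants (kJ/mol/A^2, kJ/mol/rad^2)
#' @return callable `x -> list(energy, gradient, hessian)`
#' @export
torsion_oracle <- function(mol, quad, terms, k_bond = 2000, k_angle = 300) {
  stopifnot(all(terms$p >= 1))
  quad <- as.integer(quad)
  ics <- build_internal_coordinates(mol)
  q0 <- internal_values(mol$coordinates, ics)
  nb <- nrow(ics$bonds); na <- nrow(ics$angles); nd <- nrow(ics$dihedrals)
  # locate the torsion coordinate for quad (either orientation)
  drow <- which((ics$dihedrals$j == quad[2] & ics$dihedrals$k == quad[3] &
                   ics$dihedrals$i == quad[1] & ics$dihedrals$l == quad[4]) |
                  (ics$dihedrals$j == quad[3] & ics$dihedrals$k == quad[2] &
                     ics$dihedrals$i == quad[4] & ics$dihedrals$l == quad[1]))
  if (!length(drow)) stop("quad is not a proper dihedral of the template")
  tor <- nb + na + drow[1]
  n <- n_atoms(mol)

  # per-coordinate potential derivatives V'(q_m), V''(q_m)
  derivs <- function(q) {
    V <- 0
    d1 <- numeric(nb + na + nd); d2 <- numeric(nb + na + nd)
    for (m in seq_len(nb)) {
      dq <- q[m] - q0[m]
      V <- V + 0.5 * k_bond * dq^2; d1[m] <- k_bond * dq; d2[m] <- k_bond
    }
    for (m in nb + seq_len(na)) {
      dq <- q[m] - q0[m]
      V <- V + 0.5 * k_angle * dq^2; d1[m] <- k_angle * dq; d2[m] <- k_angle
    }
    phi <- q[tor]
    V <- V + sum(terms$A * (1 + cos(terms$p * phi - terms$phi0)))
    d1[tor] <- d1[tor] + sum(-terms$A * terms$p * sin(terms$p * phi - terms$phi0))
    d2[tor] <- d2[tor] + sum(-terms$A * terms$p^2 * cos(terms$p * phi - terms$phi0))
    list(V = V, d1 = d1, d2 = d2)
  }

  function(x, need = "all") {
    q <- internal_values(x, ics)
    dv <- derivs(q)
    if (need == "energy") return(list(energy = dv$V))
    B <- wilson_b(x, ics)
    g <- as.vector(t(B) %*% dv$d1)
    if (need != "all") {
      return(list(energy = dv$V, gradient = matrix(g, n, 3, byrow = TRUE)))
    }
    # H = B' diag(d2) B + sum_m d1_m * d2(q_m)/dx2, the latter by central FD
    H <- t(B) %*% (dv$d2 * B)
    h <- 1e-5
    for (col in seq_len(3 * n)) {
      a <- (col - 1) %/% 3 + 1; d <- (col - 1) %% 3 + 1
      xp <- x; xp[a, d] <- xp[a, d] + h
      xm <- x; xm[a, d] <- xm[a, d] - h
      dB <- (wilson_b(xp, ics) - wilson_b(xm, ics)) / (2 * h)
      H[, col] <- H[, col] + as.vector(t(dB) %*% dv$d1)
    }
    H <- (H + t(H)) / 2
    list(energy = dv$V, gradient = matrix(g, n, 3, byrow = TRUE), hessian = H)
  }
}

#' Synthetic torsion scan from a known cosine series
#'
#' Angles are equidistant over 360 degrees (no duplicate endpoint); energies
#' are the series values plus optional i.i.d. Gaussian noise.
#'
#' @param quad 0-based quadruple label for the scan
#' @param terms data.frame `A`, `p`, `phi0` generating the curve
#' @param n_points number of points (>= 4; default 19)
#' @param noise_sd Gaussian noise standard deviation, kJ/mol
#' @param seed RNG seed
#' @param mol optional `molecule`: when given, rigid-rotation geometries are
#'   attached to the scan
#' @return a `dihedral_scan`
#' @export
synthetic_scan <- function(quad, terms, n_points = 19L, noise_sd = 0,
                           seed = NULL, mol = NULL) {
  stopifnot(n_points >= 4L)
  angles <- -180 + (seq_len(n_points) - 1L) * 360 / n_points
  energies <- torsion_energy(angles * pi / 180, terms)
  if (noise_sd > 0) {
    energies <- energies + with_seed(seed, stats::rnorm(n_points, sd = noise_sd))
  }
  geoms <- NULL
  if (!is.null(mol)) {
    geoms <- lapply(angles, function(a) {
      set_dihedral_in_degrees(mol, quad, a)$coordinates
    })
  }
  dihedral_scan(quad, angles, energies, geoms)
}

#' Built-in fixture molecules
#'
#' Small, valid geometries used across the test fixtures: `water`, `ethane`,
#' `butane` (anti), `biphenyl_like` (two aromatic rings joined by one
#' rotatable bond, twisted 40 degrees) and `hooh` (hydrogen peroxide, the
#' minimal one-torsion chain). Bonds are perceived before return.
#'
#' @param name one of `"water"`, `"ethane"`, `"butane"`, `"biphenyl_like"`,
#'   `"hooh"`
#' @return a `molecule` with perceived bonds
#' @export
fixture_molecule <- function(name = c("water", "ethane", "butane",
                                      "biphenyl_like", "hooh")) {
  name <- match.arg(name)
  mol <- switch(name,
    water = molecule(c("O", "H", "H"),
                     rbind(c(0, 0, 0), c(0.9572, 0, 0),
                           c(-0.2399872, 0.9266272, 0))),
    hooh = {
      # H-O-O-H with a ~112 deg torsion
      r_oo <- 1.45; r_oh <- 0.97; ang <- 100 * pi / 180
      o1 <- c(0, 0, 0); o2 <- c(r_oo, 0, 0)
      h1 <- o1 + c(r_oh * cos(pi - ang), r_oh * sin(pi - ang), 0)
      phi <- 112 * pi / 180
      h2 <- o2 + c(-r_oh * cos(pi - ang) + r_oo - r_oo,
                   r_oh * sin(pi - ang) * cos(phi),
                   r_oh * sin(pi - ang) * sin(phi))
      h2 <- o2 + c(r_oh * cos(ang), r_oh * sin(ang) * cos(phi),
                   r_oh * sin(ang) * sin(phi))
      molecule(c("H", "O", "O", "H"), rbind(h1, o1, o2, h2))
    },
    ethane = zmat_alkane(2),
    butane = zmat_alkane(4),
    biphenyl_like = biphenyl_geometry())
  perceive_bonds(mol)
}

# ideal staggered n-alkane chain built from tetrahedral geometry
zmat_alkane <- function(n_carbons) {
  r_cc <- 1.53; r_ch <- 1.09
  tet <- acos(-1 / 3)
  carbons <- matrix(0, n_carbons, 3)
  for (i in seq_len(n_carbons)[-1]) {
    # zig-zag backbone in the xz plane
    carbons[i, ] <- carbons[i - 1, ] +
      c(r_cc * sin(tet / 2) * ifelse(i %% 2 == 0, 1, 1),
        0,
        r_cc * cos(tet / 2) * ifelse(i %% 2 == 0, 1, -1))
  }
  els <- rep("C", n_carbons); coords <- carbons
  add_h <- function(coords, els, at, along) {
    list(coords = rbind(coords, coords[at, ] + r_ch * along / vnorm(along)),
         els = c(els, "H"))
  }
  for (i in seq_len(n_carbons)) {
    prev <- if (i > 1) carbons[i - 1, ] else NULL
    nxt <- if (i < n_carbons) carbons[i + 1, ] else NULL
    if (is.null(prev)) prev <- carbons[i, ] - c(r_cc * sin(tet / 2), 0,
                                                -r_cc * cos(tet / 2))
    if (is.null(nxt)) nxt <- carbons[i, ] + c(r_cc * sin(tet / 2), 0,
                                              r_cc * cos(tet / 2) *
                                                ifelse(i %% 2 == 0, -1, 1))
    # two H per carbon perpendicular to the backbone plane, tetrahedral
    u <- (carbons[i, ] - prev) / vnorm(carbons[i, ] - prev)
    v <- (nxt - carbons[i, ]) / vnorm(nxt - carbons[i, ])
    bis <- -(v - u); bis <- bis / vnorm(bis)
    nrm <- vcross(u, v); nrm <- nrm / vnorm(nrm)
    half <- (tet) / 2
    for (s in c(1, -1)) {
      dirv <- bis * cos(half) + s * nrm * sin(half)
      res <- add_h(coords, els, i, dirv)
      coords <- res$coords; els <- res$els
    }
    if (i == 1 || i == n_carbons) {
      # terminal carbon: a third H at the virtual backbone-neighbor position
      dirv <- if (i == 1) prev - carbons[i, ] else nxt - carbons[i, ]
      res <- add_h(coords, els, i, dirv)
      coords <- res$coords; els <- res$els
    }
  }
  molecule(els, coords)
}

biphenyl_geometry <- function() {
  r_cc <- 1.40; r_ch <- 1.08; r_link <- 1.48; twist <- 40 * pi / 180
  ring <- function() {
    th <- (0:5) * pi / 3
    cbind(r_cc * cos(th), r_cc * sin(th), 0)
  }
  r1 <- ring()
  # ring 1 centered so its first atom is the link carbon at origin
  r1 <- sweep(r1, 2, r1[1, ])
  r2 <- ring()
  r2 <- sweep(r2, 2, r2[1, ])
  # rotate ring 2 to face the other way and twist about the link axis (x)
  flip <- diag(c(-1, -1, 1))
  r2 <- r2 %*% flip
  rot <- rotation_matrix(c(1, 0, 0), twist)
  r2 <- r2 %*% t(rot)
  r2 <- sweep(r2, 2, c(r_link, 0, 0), `+`)
  els <- rep("C", 12)
  coords <- rbind(r1, r2)
  # H on every carbon except the two link carbons (atoms 1 and 7)
  centers <- rbind(matrix(colMeans(r1), 6, 3, byrow = TRUE),
                   matrix(colMeans(r2), 6, 3, byrow = TRUE))
  for (i in c(2:6, 8:12)) {
    dirv <- coords[i, ] - centers[i, ]
    coords <- rbind(coords, coords[i, ] + r_ch * dirv / vnorm(dirv))
    els <- c(els, "H")
  }
  molecule(els, coords)
}
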