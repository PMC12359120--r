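# Geometric primitives shared by the force-field, internal-coordinate and
# conformer modules: bond/angle/dihedral values and their analytic Cartesian
# first derivatives, dihedral rotation, and Kabsch superposition.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(v) sqrt(sum(v * v))

bond_length <- function(x, a, b) vnorm(x[b + 1L, ] - x[a + 1L, ])

# d r_ab / d x for atoms (a, b); returns 2 x 3 matrix (rows: a, b)
bond_length_grad <- function(x, a, b) {
  u <- x[b + 1L, ] - x[a + 1L, ]
  r <- vnorm(u)
  rbind(-u / r, u / r)
}

angle_value <- function(x, a, b, c) {
  u <- x[a + 1L, ] - x[b + 1L, ]
  v <- x[c + 1L, ] - x[b + 1L, ]
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, ct)))
}

# d theta / d x for angle a-b-c; 3 x 3 matrix (rows: a, b, c)
angle_grad <- function(x, a, b, c) {
  u <- x[a + 1L, ] - x[b + 1L, ]
  v <- x[c + 1L, ] - x[b + 1L, ]
  nu <- vnorm(u); nv <- vnorm(v)
  uh <- u / nu; vh <- v / nv
  ct <- max(-1, min(1, sum(uh * vh)))
  st <- sqrt(max(1 - ct^2, 1e-14))
  ga <- (ct * uh - vh) / (nu * st)
  gc <- (ct * vh - uh) / (nv * st)
  rbind(ga, -(ga + gc), gc)
}

# Signed dihedral i-j-k-l in radians, in (-pi, pi]; standard convention with
# cis = 0 and the sign given by the right-hand rule about the j->k axis.
dihedral_value <- function(x, i, j, k, l) {
  b1 <- x[j + 1L, ] - x[i + 1L, ]
  b2 <- x[k + 1L, ] - x[j + 1L, ]
  b3 <- x[l + 1L, ] - x[k + 1L, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("undefined dihedral: collinear atoms in ",
         paste(c(i, j, k, l) + 1L, collapse = "-"))
  }
  b2h <- b2 / vnorm(b2)
  phi <- atan2(sum(vcross(n1, n2) * b2h), sum(n1 * n2))
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

# d phi / d x for dihedral i-j-k-l; 4 x 3 matrix (rows: i, j, k, l).
dihedral_grad <- function(x, i, j, k, l) {
  b1 <- x[j + 1L, ] - x[i + 1L, ]
  b2 <- x[k + 1L, ] - x[j + 1L, ]
  b3 <- x[l + 1L, ] - x[k + 1L, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  nb2 <- vnorm(b2)
  gi <- -nb2 / sum(n1 * n1) * n1
  gl <-  nb2 / sum(n2 * n2) * n2
  s1 <- sum(b1 * b2) / (nb2 * nb2)
  s2 <- sum(b3 * b2) / (nb2 * nb2)
  gj <- -(1 + s1) * gi + s2 * gl
  gk <- s1 * gi - (1 + s2) * gl
  rbind(gi, gj, gk, gl)
}

wrap_angle <- function(phi) {
  # wrap to (-pi, pi]
  w <- phi - 2 * pi * round(phi / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Dihedral angle in degrees
#'
#' Returns the signed torsion angle of four bonded atoms, in (-180, 180].
#'
#' @param mol a `molecule`
#' @param quad integer vector (i, j, k, l) of 0-based atom indices
#' @return angle in degrees
#' @export
get_dihedral_in_degrees <- function(mol, quad) {
  quad <- as.integer(quad)
  if (length(unique(quad)) != 4L) stop("dihedral atoms must be four distinct atoms")
  phi <- dihedral_value(mol$coordinates, quad[1], quad[2], quad[3], quad[4]) *
    180 / pi
  if (phi <= -180) phi + 360 else phi
}

# atoms (0-based) reachable from `start` with the edge (j,k) removed
fragment_atoms <- function(mol, start, j, k) {
  adj <- adjacency_list(mol)
  seen <- rep(FALSE, n_atoms(mol))
  seen[start + 1L] <- TRUE
  queue <- start
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (b in adj[[a + 1L]]) {
      if ((a == j && b == k) || (a == k && b == j)) next
      if (!seen[b + 1L]) { seen[b + 1L] <- TRUE; queue <- c(queue, b) }
    }
  }
  which(seen) - 1L
}

bond_in_ring <- function(mol, j, k) {
  (k %in% fragment_atoms(mol, j, j, k))
}

#' Set a dihedral angle, rotating the distal fragment
#'
#' Rotates every atom on the l-side of the j-k bond rigidly about that bond so
#' the i-j-k-l torsion takes the requested value; the i-side is left untouched.
#' The axis bond must be acyclic so the rotation is well defined.
#'
#' @inheritParams get_dihedral_in_degrees
#' @param value target angle in degrees
#' @return the modified `molecule`
#' @export
set_dihedral_in_degrees <- function(mol, quad, value) {
  quad <- as.integer(quad)
  i <- quad[1]; j <- quad[2]; k <- quad[3]; l <- quad[4]
  if (!has_bond(mol, j, k)) stop("axis atoms j-k are not bonded")
  if (bond_in_ring(mol, j, k)) {
    stop("axis bond ", j + 1L, "-", k + 1L,
         " is in a ring: dihedral rotation is ill-defined")
  }
  current <- get_dihedral_in_degrees(mol, quad)
  delta <- (value - current) * pi / 180
  moving <- fragment_atoms(mol, k, j, k)
  moving <- setdiff(moving, k)  # k lies on the axis; rotation leaves it fixed
  x <- mol$coordinates
  axis <- x[k + 1L, ] - x[j + 1L, ]
  axis <- axis / vnorm(axis)
  origin <- x[k + 1L, ]
  R <- rotation_matrix(axis, delta)
  for (a in moving) {
    x[a + 1L, ] <- origin + as.vector(R %*% (x[a + 1L, ] - origin))
  }
  mol$coordinates <- x
  mol
}

# Rodrigues rotation by angle theta (right-handed) about unit axis u
rotation_matrix <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Best-fit (Kabsch) superposition RMSD between two geometries
#'
#' Both geometries are translated to their centroids and the reference is
#' rotated onto the query by the optimal proper rotation.
#'
#' @param x,y N x 3 coordinate matrices (same atom ordering)
#' @param gradient if TRUE, also return d(RMSD)/dx
#' @return the RMSD (Angstrom); with `gradient = TRUE`, a list
#'   `(rmsd, grad, aligned)` where `aligned` is y superposed onto x
#' @export
kabsch_rmsd <- function(x, y, gradient = FALSE) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(yc, xc))        # 3x3
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # rotates yc onto xc
  ya <- yc %*% t(R)
  diff <- xc - ya
  rmsd <- sqrt(sum(diff * diff) / n)
  if (!gradient) return(rmsd)
  # envelope theorem: rotation and centroids are optimal, so only the explicit
  # x-dependence contributes
  g <- if (rmsd > 1e-12) diff / (n * rmsd) else matrix(0, n, 3)
  list(rmsd = rmsd, grad = g, aligned = sweep(ya, 2, colMeans(x), `+`))
}

# aligned coordinates of y superposed onto x (centroid of x restored)
kabsch_align <- function(x, y) {
  xc_mean <- colMeans(x)
  xc <- sweep(x, 2, xc_mean)
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(yc %*% t(R), 2, xc_mean, `+`)
}
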