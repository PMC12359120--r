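#' Create an empty interpolation-mechanics database
#'
#' The IM potential approximates a surface as a distance-weighted sum of local
#' second-order Taylor expansions in internal coordinates, centered at stored
#' reference points. Weights are Shepard-type functions of the best-fit
#' Cartesian RMSD between the query and each reference geometry.
#'
#' @param ics an `internal_coordinates` set shared by all points
#' @param mode weighting mode: `"shepard"` (two-exponent, with per-point
#'   confidence radii) or `"one_part"` (plain inverse power)
#' @param exp_p,exp_q the even exponents 2p and 2q (defaults 12 and 2)
#' @return object of class `im_database`
#' @export
im_database <- function(ics, mode = c("shepard", "one_part"),
                        exp_p = 12L, exp_q = 2L) {
  mode <- match.arg(mode)
  structure(list(ics = ics, mode = mode, exp_p = as.integer(exp_p),
                 exp_q = as.integer(exp_q), points = list(),
                 version = 1L),
            class = "im_database")
}

#' @export
print.im_database <- function(x, ...) {
  cat(sprintf("im_database: %d points, %d internals, %s weights (2p=%d, 2q=%d)\n",
              length(x$points), n_internals(x$ics), x$mode, x$exp_p, x$exp_q))
  invisible(x)
}

#' Number of stored reference points
#' @param db an `im_database`
#' @return integer
#' @export
n_points <- function(db) length(db$points)

#' Second-order Taylor expansion of one reference point
#'
#' \eqn{E = E_k + g_k' dq + dq' H_k dq / 2} with dihedral components of dq
#' wrapped to (-pi, pi].
#'
#' @param q internal-coordinate vector of the query
#' @param point one element of `db$points`
#' @param ics the coordinate set (for the periodicity mask)
#' @return list `(energy, grad_q)`
#' @export
taylor_energy_gradient <- function(q, point, ics) {
  dq <- q - point$q
  per <- periodic_mask(ics)
  dq[per] <- wrap_angle(dq[per])
  hdq <- as.vector(point$H %*% dq)
  list(energy = point$E + sum(point$g * dq) + 0.5 * sum(dq * hdq),
       grad_q = point$g + hdq)
}

# raw (unnormalized) weight and its derivative wrt the distance d
raw_weight <- function(d, r, mode, exp_p, exp_q) {
  if (mode == "one_part") {
    v <- d^(-exp_p)
    dv <- -exp_p * d^(-exp_p - 1)
  } else {
    a <- (d / r)^exp_p; b <- (d / r)^exp_q
    v <- 1 / (a + b)
    dv <- -(exp_p * a / d + exp_q * b / d) * v^2
  }
  c(v, dv)
}

#' Shepard weights of a query geometry over the database points
#'
#' Distances are best-fit (Kabsch) all-atom Cartesian RMSDs. Raw weights are
#' `d^-2p` (one-part mode) or `[(d/r)^2p + (d/r)^2q]^-1` (shepard mode, with
#' the per-point confidence radius r); weights are normalized to sum to 1.
#' An exact hit (d < 1e-10) receives weight 1 with all others 0.
#'
#' @param x N x 3 query geometry, Angstrom
#' @param db an `im_database` with at least one point
#' @param gradient if TRUE, also return d(w_i)/dx as a list of N x 3 matrices
#' @return numeric weight vector; with `gradient = TRUE`, a list
#'   `(weights, grads, dists)`
#' @export
shepard_weights <- function(x, db, gradient = FALSE) {
  if (!n_points(db)) stop("empty database")
  np <- n_points(db)
  d <- numeric(np); dgrad <- vector("list", np)
  for (i in seq_len(np)) {
    kr <- kabsch_rmsd(x, db$points[[i]]$x, gradient = gradient)
    if (gradient) { d[i] <- kr$rmsd; dgrad[[i]] <- kr$grad } else d[i] <- kr
  }
  hit <- which(d < 1e-10)
  if (length(hit)) {
    w <- numeric(np); w[hit[1]] <- 1
    if (!gradient) return(w)
    return(list(weights = w,
                grads = replicate(np, matrix(0, nrow(x), 3), simplify = FALSE),
                dists = d))
  }
  raw <- vapply(seq_len(np), function(i) {
    raw_weight(d[i], db$points[[i]]$r, db$mode, db$exp_p, db$exp_q)
  }, numeric(2))
  v <- raw[1, ]; dv <- raw[2, ]
  S <- sum(v)
  w <- v / S
  if (!gradient) return(w)
  # dw_i/dx = (dv_i * dd_i/dx - w_i * sum_j dv_j * dd_j/dx) / S
  sum_term <- Reduce(`+`, lapply(seq_len(np), function(j) dv[j] * dgrad[[j]]))
  grads <- lapply(seq_len(np), function(i) {
    (dv[i] * dgrad[[i]] - w[i] * sum_term) / S
  })
  list(weights = w, grads = grads, dists = d)
}

#' Interpolation-mechanics energy and Cartesian gradient
#'
#' `E(x) = sum_i w_i(x) T_i(q(x))` with the gradient assembled from the weight
#' derivatives and the Wilson-B back-transformation of each expansion's
#' internal gradient.
#'
#' @param x N x 3 geometry, Angstrom
#' @param db an `im_database` with at least one point
#' @param gradient if FALSE, return only the energy
#' @return list `(energy, gradient)`; gradient is N x 3 kJ/mol/Angstrom
#' @export
im_energy_gradient <- function(x, db, gradient = TRUE) {
  q <- internal_values(x, db$ics)
  sw <- shepard_weights(x, db, gradient = gradient)
  w <- if (gradient) sw$weights else sw
  active <- which(w > 1e-14)
  tay <- lapply(active, function(i) taylor_energy_gradient(q, db$points[[i]],
                                                           db$ics))
  E <- sum(vapply(seq_along(active), function(t) w[active[t]] * tay[[t]]$energy,
                  numeric(1)))
  if (!gradient) return(list(energy = E, gradient = NULL))
  B <- wilson_b(x, db$ics)
  g <- matrix(0, nrow(x), 3)
  for (t in seq_along(active)) {
    i <- active[t]
    g <- g + tay[[t]]$energy * sw$grads[[i]] +
      w[i] * matrix(as.vector(t(B) %*% tay[[t]]$grad_q), ncol = 3, byrow = TRUE)
  }
  list(energy = E, gradient = g)
}

#' Add a reference point to an IM database
#'
#' Queries the oracle at `x` for energy, Cartesian gradient and Hessian,
#' transforms the derivatives into internal coordinates and appends the point.
#' Confidence radii are refreshed as each point's distance to its nearest
#' database neighbor (1.0 Angstrom while the database has a single point).
#' Geometries within 1e-6 RMSD of an existing point are rejected.
#'
#' @param x N x 3 geometry, Angstrom
#' @param oracle a callable `x -> list(energy, gradient, hessian)` in
#'   kJ/mol, kJ/mol/Angstrom, kJ/mol/Angstrom^2
#' @param db an `im_database`
#' @return the expanded database (unchanged if the point was rejected)
#' @export
add_point <- function(x, oracle, db) {
  for (p in db$points) {
    if (kabsch_rmsd(x, p$x) < 1e-6) {
      warning("add_point: geometry within 1e-6 RMSD of an existing point; rejected",
              call. = FALSE)
      return(db)
    }
  }
  o <- oracle(x)
  tr <- transform_derivatives(x, o$gradient, o$hessian, db$ics)
  db$points[[n_points(db) + 1L]] <- list(
    q = tr$q, E = o$energy, g = tr$g_int, H = tr$H_int, x = x, r = 1.0)
  refresh_radii(db)
}

# confidence radius = distance to nearest neighbor (1.0 A for a lone point)
refresh_radii <- function(db) {
  np <- n_points(db)
  if (np < 2L) {
    if (np == 1L) db$points[[1]]$r <- 1.0
    return(db)
  }
  d <- matrix(0, np, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    d[i, j] <- d[j, i] <- kabsch_rmsd(db$points[[i]]$x, db$points[[j]]$x)
  }
  diag(d) <- Inf
  for (i in seq_len(np)) db$points[[i]]$r <- min(d[i, ])
  db
}
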