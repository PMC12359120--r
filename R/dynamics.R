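# Langevin dynamics (BAOAB velocity-Verlet splitting) over an arbitrary
# potential callable x -> list(energy, gradient). Shared by the IM database
# builder and the high-temperature conformational sampler.
#
# Units: Angstrom, kJ/mol, amu, fs. With these units accelerations are
# g[kJ/mol/A] / m[amu] * .acc_unit in A/fs^2.
.acc_unit <- 1e-4  # (kJ/mol/A)/amu -> A/fs^2 conversion (1 kJ/mol = 0.01 amu A^2/fs^2)

#' Langevin dynamics driver
#'
#' Propagates a geometry on an arbitrary potential with a BAOAB integrator and
#' an Ornstein-Uhlenbeck thermostat.
#'
#' @param x0 N x 3 starting coordinates, Angstrom
#' @param masses per-atom masses, amu
#' @param potential callable `x -> list(energy, gradient)`
#' @param n_steps number of steps
#' @param dt_fs time step, fs (default 0.5)
#' @param temperature K
#' @param friction 1/ps collision rate (default 1.0)
#' @param callback optional `function(step, x, energy)` invoked every
#'   `callback_every` steps; a non-NULL return replaces the coordinates
#'   (used for restraint-style interventions and snapshot capture)
#' @param callback_every step interval for the callback
#' @return list `(x, velocities, energies)`; `energies` sampled at callback steps
#' @export
langevin_dynamics <- function(x0, masses, potential, n_steps, dt_fs = 0.5,
                              temperature = 300, friction = 1.0,
                              callback = NULL, callback_every = 10L) {
  n <- nrow(x0)
  x <- x0
  kT <- .kB * temperature
  # velocity scale: kT[kJ/mol] -> amu A^2/fs^2 via .acc_unit
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(kT * .acc_unit / masses)), n, 3)
  gamma_fs <- friction * 1e-3
  c1 <- exp(-gamma_fs * dt_fs)
  c2 <- sqrt(1 - c1^2)
  pot <- potential(x)
  g <- pot$gradient
  energies <- numeric(0)
  for (step in seq_len(n_steps)) {
    v <- v - 0.5 * dt_fs * .acc_unit * g / masses
    x <- x + 0.5 * dt_fs * v
    v <- c1 * v + c2 * matrix(stats::rnorm(3 * n, sd = sqrt(kT * .acc_unit / masses)),
                              n, 3)
    x <- x + 0.5 * dt_fs * v
    pot <- potential(x)
    if (!all(is.finite(pot$gradient)) || !is.finite(pot$energy)) {
      stop("dynamics blow-up at step ", step, ": non-finite energy or gradient")
    }
    g <- pot$gradient
    v <- v - 0.5 * dt_fs * .acc_unit * g / masses
    if (max(abs(v)) * dt_fs > 2.0) {
      stop("dynamics blow-up at step ", step, ": displacement > 2 A per step")
    }
    if (!is.null(callback) && step %% callback_every == 0L) {
      res <- callback(step, x, if (is.null(pot$base_energy)) pot$energy
                               else pot$base_energy)
      energies <- c(energies, pot$energy)
      if (!is.null(res) && is.matrix(res)) {
        x <- res
        pot <- potential(x)
        g <- pot$gradient
      }
    }
  }
  list(x = x, velocities = v, energies = energies)
}

# Gradient-descent relaxation with backtracking line search on an arbitrary
# potential; optionally keeps a dihedral frozen by re-imposing it after each
# step. Converges at max|g| < gtol (projected gradient when frozen).
relax_geometry <- function(mol, potential, frozen_quad = NULL,
                           frozen_value = NULL, gtol = 0.1, max_iter = 2000L) {
  x <- mol$coordinates
  impose <- function(x) {
    if (is.null(frozen_quad)) return(x)
    m <- mol; m$coordinates <- x
    set_dihedral_in_degrees(m, frozen_quad, frozen_value)$coordinates
  }
  x <- impose(x)
  pot <- potential(x)
  step <- 1e-3
  for (it in seq_len(max_iter)) {
    g <- pot$gradient
    if (!is.null(frozen_quad)) {
      # project out the frozen-dihedral direction
      dg <- matrix(0, nrow(x), 3)
      ids <- frozen_quad + 1L
      dg[ids, ] <- dihedral_grad(x, frozen_quad[1], frozen_quad[2],
                                 frozen_quad[3], frozen_quad[4])
      dgv <- as.vector(dg)
      gv <- as.vector(g) - sum(as.vector(g) * dgv) / sum(dgv * dgv) * dgv
      g <- matrix(gv, nrow(x), 3)
    }
    if (max(abs(g)) < gtol) {
      mol$coordinates <- x
      return(mol)
    }
    accepted <- FALSE
    for (bt in 1:40) {
      xn <- impose(x - step * g)
      potn <- potential(xn)
      if (is.finite(potn$energy) && potn$energy < pot$energy) {
        x <- xn; pot <- potn
        step <- min(step * 1.5, 0.05)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      if (max(abs(g)) < 10 * gtol) { mol$coordinates <- x; return(mol) }
      stop("relaxation failed to make progress (max|g| = ",
           format(max(abs(g)), digits = 3), " kJ/mol/A after ", it, " iterations)")
    }
  }
  stop("relaxation did not converge within ", max_iter, " iterations (max|g| = ",
       format(max(abs(pot$gradient)), digits = 3), ")")
}
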