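#' Settings for adaptive IM database construction
#'
#' Defaults follow the torsion-scan construction protocol: 10 seed structures
#' equidistant over the full rotation, restrained sampling dynamics within
#' +/- 18 degrees of each seed, an 8.4 kJ/mol IM-vs-oracle energy threshold
#' for adding points, and termination of a sampling run after 7.5 ps without
#' additions.
#'
#' @param energy_threshold kJ/mol; a sampled structure whose IM error exceeds
#'   it is added to the database (default 8.4)
#' @param max_points hard cap on database size (default 50)
#' @param no_add_window_ps terminate a sampling run after this long without an
#'   addition (default 7.5 ps)
#' @param n_seed_structures equidistant dihedral seeds (default 10)
#' @param displacement_restraint degrees; flat-bottom dihedral restraint
#'   half-width around each seed (default 18)
#' @param dt_fs integration step (default 0.5 fs)
#' @param temperature sampling temperature, K (default 300)
#' @param check_every compare IM vs oracle every this many steps (default 10)
#' @param seed RNG seed for the sampling dynamics
#' @return a list of class `im_build_settings`
#' @export
im_build_settings <- function(energy_threshold = 8.4, max_points = 50L,
                              no_add_window_ps = 7.5, n_seed_structures = 10L,
                              displacement_restraint = 18, dt_fs = 0.5,
                              temperature = 300, check_every = 10L,
                              seed = NULL) {
  stopifnot(energy_threshold > 0, no_add_window_ps > 0,
            n_seed_structures >= 1L, displacement_restraint > 0)
  structure(list(energy_threshold = energy_threshold,
                 max_points = as.integer(max_points),
                 no_add_window_ps = no_add_window_ps,
                 n_seed_structures = as.integer(n_seed_structures),
                 displacement_restraint = displacement_restraint,
                 dt_fs = dt_fs, temperature = temperature,
                 check_every = as.integer(check_every), seed = seed),
            class = "im_build_settings")
}

# call an oracle at the requested derivative level; oracles written without a
# `need` argument are called plainly
oracle_call <- function(oracle, x, need = "all") {
  if ("need" %in% names(formals(oracle))) oracle(x, need) else oracle(x)
}

# flat-bottom harmonic restraint on a dihedral: zero within +/- width of
# center, harmonic outside (k in kJ/mol/rad^2)
restraint_potential <- function(base_potential, mol, quad, center_deg,
                                width_deg, k = 500) {
  function(x) {
    pot <- base_potential(x)
    pot$base_energy <- pot$energy   # restraint-free energy, for IM-error checks
    phi <- dihedral_value(x, quad[1], quad[2], quad[3], quad[4])
    dphi <- wrap_angle(phi - center_deg * pi / 180)
    w <- width_deg * pi / 180
    if (abs(dphi) > w) {
      excess <- abs(dphi) - w
      pot$energy <- pot$energy + 0.5 * k * excess^2
      dVdphi <- k * excess * sign(dphi)
      dg <- dihedral_grad(x, quad[1], quad[2], quad[3], quad[4]) * dVdphi
      ids <- quad + 1L
      pot$gradient[ids, ] <- pot$gradient[ids, ] + dg
    }
    pot
  }
}

#' Adaptive construction of an IM database along a key torsion
#'
#' Seeds the database with `n_seed_structures` oracle-relaxed geometries
#' placed equidistantly over the full 360-degree rotation of `key_dihedral`
#' (the dihedral is frozen during each relaxation). After each seed is added,
#' restrained Langevin dynamics on the current IM surface samples its
#' neighborhood (flat-bottom restraint of +/- `displacement_restraint`
#' degrees); whenever a sampled structure's |E_IM - E_oracle| exceeds
#' `energy_threshold` the structure is added and the no-addition timer resets.
#' A sampling run ends after `no_add_window_ps` without additions; the build
#' ends when all seeds are processed or `max_points` is reached.
#'
#' @param mol a `molecule` with perceived bonds
#' @param oracle callable `x -> list(energy, gradient, hessian)`
#' @param key_dihedral 0-based quadruple of the scanned torsion
#' @param settings an [im_build_settings()] object
#' @param db optionally, an existing database to extend
#' @return the database, with a `build_log` attribute (data.frame: seed,
#'   seed_angle, points_added, ps_simulated)
#' @export
build_database <- function(mol, oracle, key_dihedral,
                           settings = im_build_settings(), db = NULL) {
  key_dihedral <- as.integer(key_dihedral)
  if (is.null(db)) {
    ics <- build_internal_coordinates(mol)
    db <- im_database(ics)
  }
  if (!is.null(settings$seed)) set.seed(settings$seed)
  masses <- atomic_mass(mol$elements)
  start_angle <- get_dihedral_in_degrees(mol, key_dihedral)
  seed_angles <- start_angle + (seq_len(settings$n_seed_structures) - 1L) *
    360 / settings$n_seed_structures
  log <- NULL
  window_steps <- ceiling(settings$no_add_window_ps * 1000 /
                            (settings$dt_fs * settings$check_every))
  for (s in seq_along(seed_angles)) {
    if (n_points(db) >= settings$max_points) break
    target <- wrap_angle(seed_angles[s] * pi / 180) * 180 / pi
    seed_mol <- set_dihedral_in_degrees(mol, key_dihedral, target)
    seed_mol <- relax_geometry(seed_mol, function(x) {
      oracle_call(oracle, x, "gradient")
    }, frozen_quad = key_dihedral, frozen_value = target)
    n_before <- n_points(db)
    db <- add_point(seed_mol$coordinates, oracle, db)

    # restrained sampling on the current IM surface
    added_tick <- 0L; tick <- 0L
    env <- environment()
    sampler_cb <- function(step, x, energy) {
      tick <- get("tick", env) + 1L
      assign("tick", tick, env)
      eo <- oracle_call(oracle, x, "energy")$energy
      if (abs(energy - eo) > settings$energy_threshold &&
          n_points(get("db", env)) < settings$max_points) {
        grown <- suppressWarnings(add_point(x, oracle, get("db", env)))
        if (n_points(grown) > n_points(get("db", env))) {
          assign("db", grown, env)
          assign("added_tick", tick, env)
        }
      }
      NULL
    }
    steps_run <- 0L
    repeat {
      if (n_points(db) >= settings$max_points) break
      chunk <- settings$check_every * min(window_steps, 500L)
      pot_im <- function(x) im_energy_gradient(x, db)
      pot <- restraint_potential(pot_im, mol, key_dihedral, target,
                                 settings$displacement_restraint)
      run <- langevin_dynamics(seed_mol$coordinates, masses, pot,
                               n_steps = chunk, dt_fs = settings$dt_fs,
                               temperature = settings$temperature,
                               callback = sampler_cb,
                               callback_every = settings$check_every)
      seed_mol$coordinates <- run$x
      steps_run <- steps_run + chunk
      if (tick - added_tick >= window_steps) break
    }
    log <- rbind(log, data.frame(seed = s, seed_angle = target,
                                 points_added = n_points(db) - n_before,
                                 ps_simulated = steps_run * settings$dt_fs / 1000))
  }
  attr(db, "build_log") <- log
  db
}

# validation run: Langevin dynamics on the IM surface, recording
# |E_IM - E_oracle| and the offending structures
im_validation_run <- function(mol, db, oracle, settings, n_steps = NULL,
                              start = NULL) {
  masses <- atomic_mass(mol$elements)
  if (is.null(n_steps)) {
    n_steps <- ceiling(settings$no_add_window_ps * 1000 / settings$dt_fs)
  }
  errs <- numeric(0)
  structures <- list()
  cb <- function(step, x, energy) {
    err <- abs(energy - oracle_call(oracle, x, "energy")$energy)
    errs <<- c(errs, err)
    if (err > settings$energy_threshold) structures[[length(structures) + 1L]] <<- x
    NULL
  }
  starts <- if (is.null(start)) lapply(db$points, `[[`, "x") else list(start)
  seg <- max(ceiling(n_steps / length(starts)), settings$check_every)
  for (x0 in starts) {
    langevin_dynamics(x0, masses, function(x) im_energy_gradient(x, db),
                      n_steps = seg, dt_fs = settings$dt_fs,
                      temperature = settings$temperature, callback = cb,
                      callback_every = settings$check_every)
  }
  list(max_error = if (length(errs)) max(errs) else 0, errors = errs,
       structures = structures)
}

#' Confirm (and, if needed, expand) the quality of an IM database
#'
#' Runs a test simulation on the IM surface; every sampled structure whose
#' IM-vs-oracle energy error exceeds the threshold is added to the database,
#' and the test repeats until a full pass produces no additions.
#'
#' @inheritParams build_database
#' @param db the database under test
#' @param max_iterations cap on expansion rounds (default 10)
#' @return list `(db, report)`; `report` is a data.frame with per-iteration
#'   `max_error` and `points_added`
#' @export
confirm_database_quality <- function(mol, db, oracle,
                                     settings = im_build_settings(),
                                     max_iterations = 10L) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  report <- NULL
  for (it in seq_len(max_iterations)) {
    val <- im_validation_run(mol, db, oracle, settings)
    added <- 0L
    for (x in val$structures) {
      nb <- n_points(db)
      db <- suppressWarnings(add_point(x, oracle, db))
      added <- added + (n_points(db) - nb)
    }
    report <- rbind(report, data.frame(iteration = it,
                                       max_error = val$max_error,
                                       points_added = added))
    if (added == 0L) {
      return(list(db = db, report = report, converged = TRUE))
    }
  }
  cond <- simpleError(paste0("confirm_database_quality: no convergence within ",
                             max_iterations, " iterations"))
  cond$db <- db
  cond$report <- report
  stop(cond)
}
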