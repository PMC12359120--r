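test_that("internal-coordinate sets match an independent graph enumeration", {
  w <- fixture_molecule("water")
  iw <- build_internal_coordinates(w)
  expect_equal(nrow(iw$bonds), 2L)
  expect_equal(nrow(iw$angles), 1L)
  expect_equal(nrow(iw$dihedrals), 0L)

  m <- fixture_molecule("butane")
  ics <- build_internal_coordinates(m)
  # independent walk over the bond graph
  adj <- lapply(seq_len(n_atoms(m)), function(a) integer(0))
  for (r in seq_len(nrow(m$bonds))) {
    a <- m$bonds[r, 1] + 1L; b <- m$bonds[r, 2] + 1L
    adj[[a]] <- c(adj[[a]], b - 1L); adj[[b]] <- c(adj[[b]], a - 1L)
  }
  n_ang <- sum(vapply(adj, function(nb) choose(length(nb), 2), numeric(1)))
  n_dih <- 0
  for (r in seq_len(nrow(m$bonds))) {
    j <- m$bonds[r, 1]; k <- m$bonds[r, 2]
    n_dih <- n_dih + (length(adj[[j + 1L]]) - 1L) * (length(adj[[k + 1L]]) - 1L)
  }
  expect_equal(nrow(ics$bonds), nrow(m$bonds))
  expect_equal(nrow(ics$angles), n_ang)
  expect_equal(nrow(ics$dihedrals), n_dih)

  # deterministic ordering across calls
  expect_identical(build_internal_coordinates(m), ics)
})

test_that("Wilson B rows are the internal-coordinate derivatives", {
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  x <- m$coordinates
  B <- wilson_b(x, ics)
  Bfd <- t(vapply(seq_len(ffcraft:::n_internals(ics)), function(mth) {
    as.vector(t(fd_gradient(function(xx) internal_values(xx, ics)[mth], x,
                            h = 1e-6)))
  }, numeric(12)))
  expect_lt(max(abs(B - Bfd)), 1e-7)
})

test_that("derivative transforms satisfy the projection identities", {
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  x <- set_dihedral_in_degrees(m, c(0, 1, 2, 3), 75)$coordinates
  o <- orc(x)
  tr <- transform_derivatives(x, o$gradient, o$hessian, ics)
  B <- wilson_b(x, ics)
  # back-projection reproduces the (rotation/translation-free) gradient
  expect_lt(max(abs(as.vector(t(B) %*% tr$g_int) - as.vector(t(o$gradient)))),
            1e-8)
  # zero derivatives transform to zero
  z <- transform_derivatives(x, matrix(0, 4, 3), matrix(0, 12, 12), ics)
  expect_true(all(z$g_int == 0))
  expect_true(all(z$H_int == 0))
  expect_equal(z$q, internal_values(x, ics))
})

test_that("Taylor expansion is exact at its center and wraps dihedrals", {
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  db <- add_point(m$coordinates, orc, im_database(ics))
  p <- db$points[[1]]
  te <- taylor_energy_gradient(p$q, p, ics)
  expect_equal(te$energy, p$E)
  expect_equal(te$grad_q, p$g)

  # wrapped periodic displacement: 179 vs -179 deg differ by 2 deg
  q1 <- p$q; q1[length(q1)] <- 179 * pi / 180
  p2 <- p; p2$q[length(p2$q)] <- -179 * pi / 180
  p2$g[] <- 0; p2$H[] <- 0; p2$E <- 0
  # quadratic in the wrapped displacement only: use H = I on the dihedral
  p2$H[length(q1), length(q1)] <- 1
  e <- taylor_energy_gradient(q1, p2, ics)$energy
  expect_equal(e, 0.5 * (2 * pi / 180)^2, tolerance = 1e-12)
})

test_that("Taylor expansion of a quadratic surface is exact everywhere", {
  set.seed(40)
  m <- fixture_molecule("water")
  ics <- build_internal_coordinates(m)
  # oracle exactly quadratic in the internals
  q0 <- internal_values(m$coordinates, ics)
  kq <- c(900, 800, 120)
  quad_oracle <- function(x, need = "all") {
    q <- internal_values(x, ics)
    B <- wilson_b(x, ics)
    d1 <- kq * (q - q0)
    g <- as.vector(t(B) %*% d1)
    out <- list(energy = 0.5 * sum(kq * (q - q0)^2),
                gradient = matrix(g, 3, 3, byrow = TRUE))
    if (need == "all") {
      H <- t(B) %*% (kq * B)
      h <- 1e-5
      for (col in 1:9) {
        a <- (col - 1) %/% 3 + 1; d <- (col - 1) %% 3 + 1
        xp <- x; xp[a, d] <- xp[a, d] + h
        xm <- x; xm[a, d] <- xm[a, d] - h
        dB <- (wilson_b(xp, ics) - wilson_b(xm, ics)) / (2 * h)
        H[, col] <- H[, col] + as.vector(t(dB) %*% d1)
      }
      out$hessian <- (H + t(H)) / 2
    }
    out
  }
  db <- add_point(m$coordinates, quad_oracle, im_database(ics))
  for (t in 1:10) {
    x <- m$coordinates + matrix(rnorm(9, 0, 0.05), 3, 3)
    got <- im_energy_gradient(x, db, gradient = FALSE)$energy
    expect_equal(got, quad_oracle(x, "energy")$energy, tolerance = 1e-5)
  }
})

test_that("Shepard weights: exact hits, normalization, symmetry, formula", {
  set.seed(41)
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  db <- im_database(ics)
  for (a in c(-120, 0, 60, 150)) {
    db <- add_point(set_dihedral_in_degrees(m, c(0, 1, 2, 3), a)$coordinates,
                    orc, db)
  }
  # exact hit
  w <- shepard_weights(db$points[[3]]$x, db)
  expect_equal(w, c(0, 0, 1, 0))
  # normalization at random queries
  for (t in 1:100) {
    x <- db$points[[sample(4, 1)]]$x + matrix(rnorm(12, 0, 0.08), 4, 3)
    w <- shepard_weights(x, db)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  # brute-force re-evaluation of the two-part formula
  x <- db$points[[2]]$x + matrix(rnorm(12, 0, 0.1), 4, 3)
  d <- vapply(db$points, function(p) kabsch_rmsd(x, p$x), numeric(1))
  r <- vapply(db$points, `[[`, numeric(1), "r")
  v <- 1 / ((d / r)^12 + (d / r)^2)
  expect_equal(shepard_weights(x, db), v / sum(v), tolerance = 1e-12)

  # two stored points at equal distance share the weight equally
  m2 <- set_dihedral_in_degrees(m, c(0, 1, 2, 3), 0)
  db2 <- im_database(ics)
  db2 <- add_point(set_dihedral_in_degrees(m, c(0, 1, 2, 3), 40)$coordinates,
                   orc, db2)
  db2 <- add_point(set_dihedral_in_degrees(m, c(0, 1, 2, 3), -40)$coordinates,
                   orc, db2)
  w2 <- shepard_weights(m2$coordinates, db2)
  expect_equal(w2, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("one-part weighting mode follows the inverse-power formula", {
  set.seed(42)
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  db <- im_database(ics, mode = "one_part", exp_p = 6L)
  for (a in c(-90, 90)) {
    db <- add_point(set_dihedral_in_degrees(m, c(0, 1, 2, 3), a)$coordinates,
                    orc, db)
  }
  x <- db$points[[1]]$x + matrix(rnorm(12, 0, 0.07), 4, 3)
  d <- vapply(db$points, function(p) kabsch_rmsd(x, p$x), numeric(1))
  v <- d^(-6)
  expect_equal(shepard_weights(x, db), v / sum(v), tolerance = 1e-12)
})

test_that("IM potential interpolates through its data and has a consistent gradient", {
  set.seed(43)
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  db <- im_database(ics)
  for (a in c(-140, -60, 20, 100, 180)) {
    db <- add_point(set_dihedral_in_degrees(m, c(0, 1, 2, 3), a)$coordinates,
                    orc, db)
  }
  # single-point database equals that point's Taylor expansion
  db1 <- im_database(ics)
  db1 <- add_point(m$coordinates, orc, db1)
  x <- m$coordinates + matrix(rnorm(12, 0, 0.05), 4, 3)
  tay <- taylor_energy_gradient(internal_values(x, ics), db1$points[[1]], ics)
  expect_equal(im_energy_gradient(x, db1, gradient = FALSE)$energy, tay$energy)

  # interpolation-through-data at every stored geometry
  for (p in db$points) {
    eg <- im_energy_gradient(p$x, db)
    expect_equal(eg$energy, p$E, tolerance = 1e-9)
    expect_lt(max(abs(eg$gradient - orc(p$x, "gradient")$gradient)), 1e-6)
  }

  # analytic gradient vs finite differences at random geometries
  for (t in 1:8) {
    x <- db$points[[sample(5, 1)]]$x + matrix(rnorm(12, 0, 0.06), 4, 3)
    eg <- im_energy_gradient(x, db)
    gfd <- fd_gradient(function(xx) {
      im_energy_gradient(xx, db, gradient = FALSE)$energy
    }, x)
    expect_lt(max(abs(eg$gradient - gfd)), 1e-5)
  }

  # rigid-motion invariance of the energy
  x <- db$points[[2]]$x + matrix(rnorm(12, 0, 0.04), 4, 3)
  R <- ffcraft:::rotation_matrix(c(0, 0.8, 0.6), 1.3)
  xr <- x %*% t(R) + matrix(c(-2, 4, 1), 4, 3, byrow = TRUE)
  expect_equal(im_energy_gradient(xr, db, gradient = FALSE)$energy,
               im_energy_gradient(x, db, gradient = FALSE)$energy,
               tolerance = 1e-10)
})

test_that("add_point appends, transforms consistently, and rejects duplicates", {
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  db <- im_database(ics)
  db <- add_point(m$coordinates, orc, db)
  expect_equal(n_points(db), 1L)
  eg <- im_energy_gradient(m$coordinates, db)
  expect_equal(eg$energy, orc(m$coordinates, "energy")$energy)

  # directional-derivative check of the transformed g/H through the Taylor form
  set.seed(44)
  dxs <- matrix(rnorm(12, 0, 1), 4, 3)
  dxs <- dxs / sqrt(sum(dxs^2))
  h <- 1e-4
  e_p <- im_energy_gradient(m$coordinates + h * dxs, db, gradient = FALSE)$energy
  e_m <- im_energy_gradient(m$coordinates - h * dxs, db, gradient = FALSE)$energy
  o_p <- orc(m$coordinates + h * dxs, "energy")$energy
  o_m <- orc(m$coordinates - h * dxs, "energy")$energy
  expect_equal((e_p - e_m) / (2 * h), (o_p - o_m) / (2 * h), tolerance = 1e-4)

  expect_warning(db2 <- add_point(m$coordinates, orc, db), "rejected")
  expect_equal(n_points(db2), 1L)
})

test_that("database container round-trips bit-identically and validates input", {
  m <- fixture_molecule("hooh")
  ics <- build_internal_coordinates(m)
  orc <- torsion_oracle(m, c(0, 1, 2, 3), hooh_oracle_terms())
  db <- im_database(ics)
  for (a in seq(-180, 150, by = 30)) {
    db <- suppressWarnings(
      add_point(set_dihedral_in_degrees(m, c(0, 1, 2, 3), a)$coordinates,
                orc, db))
  }
  expect_equal(n_points(db), 12L)
  td <- withr::local_tempdir()

  f <- file.path(td, "db.h5")
  save_database(db, f)
  db2 <- load_database(f)
  expect_identical(db2$points, db$points)
  expect_identical(db2$ics, db$ics)
  expect_identical(db2$mode, db$mode)

  # default filename
  withr::local_dir(td)
  save_database(db)
  expect_true(file.exists("im_database.h5"))

  # foreign and truncated files
  writeLines("not a database", file.path(td, "foreign.h5"))
  expect_error(load_database(file.path(td, "foreign.h5")), "magic")
  raw <- readBin(f, "raw", 60)
  writeBin(raw, file.path(td, "trunc.h5"))
  expect_error(load_database(file.path(td, "trunc.h5")), "truncated|corrupt")
  expect_error(load_database(file.path(td, "absent.h5")), "no such")
})
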