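test_that("scan files round-trip with unit conversion and fail on malformed frames", {
  m <- fixture_molecule("butane")
  angles <- c(-120, 0, 120)
  geoms <- lapply(angles, function(a) {
    set_dihedral_in_degrees(m, c(0, 1, 2, 3), a)$coordinates
  })
  scan <- dihedral_scan(c(0, 1, 2, 3), angles,
                        torsion_energy(angles * pi / 180, gen_terms()), geoms)
  f <- withr::local_tempfile(fileext = ".xyz")

  write_scan_file(scan, m$elements, f, unit = "kj/mol")
  back <- read_scan_file(f)
  expect_length(back$angles, 3)
  expect_equal(back$quad, scan$quad)
  expect_equal(back$energies, scan$energies, tolerance = 1e-9)
  expect_equal(back$geometries[[2]], scan$geometries[[2]], tolerance = 1e-9)

  # hartree energies are converted by 2625.4996... kJ/mol per hartree
  write_scan_file(scan, m$elements, f, unit = "hartree")
  back_h <- read_scan_file(f)
  expect_equal(back_h$energies, scan$energies, tolerance = 1e-6)

  # frame with a different atom count
  lines <- readLines(f)
  block2 <- grep("^14$", lines)[2]
  lines[block2] <- "13"
  writeLines(c(lines[1:(block2 + 14)], lines[(block2 + 16):length(lines)]), f)
  expect_error(read_scan_file(f), "atom count")

  # unparsable comment line
  writeLines(c("2", "no metadata here", "H 0 0 0", "H 1 0 0"), f)
  expect_error(read_scan_file(f), "frame 1")
})

test_that("mm_scan is the pointwise MM curve, zero-shifted", {
  m <- fixture_molecule("butane")
  ff <- toy_ff(m)
  # amplitudes all zero and no nonbonded -> flat curve
  ff_flat <- forcefield_from_geometry(m)         # epsilon = 0, charges = 0
  ff_flat <- add_dihedral_term(ff_flat, c(0, 1, 2, 3), 0, 3, 0)
  scan <- synthetic_scan(c(0, 1, 2, 3), gen_terms(), n_points = 7, mol = m)
  expect_equal(mm_scan(m, ff_flat, scan), rep(0, 7), tolerance = 1e-9)

  # pointwise equality with direct evaluation, and exact zero minimum
  ff2 <- add_dihedral_term(ff, c(0, 1, 2, 3), 4, 3, 0)
  curve <- mm_scan(m, ff2, scan)
  expect_equal(min(curve), 0)
  direct <- vapply(seq_along(scan$angles), function(f) {
    mm <- m; mm$coordinates <- scan$geometries[[f]]
    evaluate_mm(mm, ffcraft:::cache_pairs(ff2), gradient = FALSE)$energy[["total"]]
  }, numeric(1))
  expect_equal(curve, direct - min(direct), tolerance = 1e-10)
})

test_that("fit_dihedral recovers generating amplitudes and matches the
           normal-equations oracle", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  gen <- gen_terms()
  ff <- toy_ff(m)
  scan0 <- synthetic_scan(quad, gen, n_points = 19, mol = m)
  rest <- mm_scan(m, ff, scan0)
  ref <- dihedral_scan(quad, scan0$angles,
                       rest + torsion_energy(scan0$angles * pi / 180, gen),
                       scan0$geometries)
  ffq <- add_fit_term(ff, quad, 3, 0)
  ffq <- add_fit_term(ffq, quad, 1, 180)
  fit <- fit_dihedral(ffq, quad, m, ref)
  rep <- attr(fit, "fit_report")
  expect_lt(max(abs(sort(unname(rep$amplitudes)) - sort(gen$A))), 1e-10)
  expect_lt(rep$rmse, 1e-10)

  # independent normal-equations solve on the raw cosine basis
  phi <- ref$angles * pi / 180
  X <- cbind(1 + cos(3 * phi), 1 + cos(phi - pi), 1)
  y <- ref$energies - rest
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(sort(unname(rep$amplitudes)), sort(beta[1:2]), tolerance = 1e-8)
})

test_that("fit is a fixed point on its own curve and idempotent", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  ff <- toy_ff(m)
  ff <- add_dihedral_term(ff, quad, 5.5, 3, 0)
  ff <- add_dihedral_term(ff, quad, 1.2, 2, pi / 2)
  scan0 <- synthetic_scan(quad, gen_terms(), n_points = 13, mol = m)
  self <- dihedral_scan(quad, scan0$angles, mm_scan(m, ff, scan0),
                        scan0$geometries)
  fit1 <- fit_dihedral(ff, quad, m, self)
  expect_equal(fit1$dihedrals$A, ff$dihedrals$A, tolerance = 1e-9)
  expect_lt(attr(fit1, "fit_report")$rmse, 1e-9)
  fit2 <- fit_dihedral(fit1, quad, m, self)
  expect_equal(fit2$dihedrals$A, fit1$dihedrals$A, tolerance = 1e-10)
})

test_that("fit is invariant to point ordering and constant reference shifts", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  ff <- add_fit_term(toy_ff(m), quad, 3, 0)
  scan0 <- synthetic_scan(quad, data.frame(A = 4, p = 3, phi0 = 0),
                          n_points = 11, mol = m)
  base <- dihedral_scan(quad, scan0$angles,
                        mm_scan(m, toy_ff(m), scan0) +
                          torsion_energy(scan0$angles * pi / 180,
                                         data.frame(A = 4, p = 3, phi0 = 0)),
                        scan0$geometries)
  a1 <- attr(fit_dihedral(ff, quad, m, base), "fit_report")$amplitudes

  set.seed(30)
  perm <- sample(length(base$angles))
  shuffled <- dihedral_scan(quad, base$angles[perm], base$energies[perm],
                            base$geometries[perm])
  a2 <- attr(fit_dihedral(ff, quad, m, shuffled), "fit_report")$amplitudes
  expect_equal(unname(a1), unname(a2), tolerance = 1e-9)

  shifted <- dihedral_scan(quad, base$angles, base$energies + 37.5,
                           base$geometries)
  a3 <- attr(fit_dihedral(ff, quad, m, shifted), "fit_report")$amplitudes
  expect_equal(unname(a1), unname(a3), tolerance = 1e-9)
})

test_that("fit_extrema interpolates the selected extrema when unknowns suffice", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  gen <- data.frame(A = c(5, 2), p = c(2, 1), phi0 = c(0, 0))
  ff <- forcefield_from_geometry(m)  # no nonbonded background
  ff <- add_fit_term(ff, quad, 2, 0)
  ff <- add_fit_term(ff, quad, 1, 0)
  scan <- synthetic_scan(quad, gen, n_points = 24, mol = m)
  fit <- fit_dihedral(ff, quad, m, scan, fit_extrema = TRUE)
  sel <- which(ffcraft:::periodic_extrema(scan$angles, scan$energies))
  after <- mm_scan(m, fit, scan)
  resid <- (scan$energies - after)[sel]
  expect_lt(max(abs(resid - mean(resid))), 1e-8)  # exact up to the free offset
})

test_that("fit errors on underdetermined or rank-deficient bases", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  ff <- add_fit_term(toy_ff(m), quad, 3, 0)
  tiny <- synthetic_scan(quad, gen_terms(), n_points = 4, mol = m)
  short <- dihedral_scan(quad, tiny$angles[1], tiny$energies[1],
                         tiny$geometries[1])
  expect_error(fit_dihedral(ff, quad, m, short), "underdetermined")
  expect_error(fit_dihedral(forcefield_from_geometry(m), quad, m, tiny),
               "no torsion term")
})

test_that("add_fit_term appends silently (A = 0) and rejects duplicates", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  ff <- toy_ff(m)
  ff <- add_dihedral_term(ff, quad, 4, 3, 0)
  scan <- synthetic_scan(quad, gen_terms(), n_points = 9, mol = m)
  before <- mm_scan(m, ff, scan)
  ff2 <- add_fit_term(ff, quad, 2, 180)
  expect_equal(mm_scan(m, ff2, scan), before, tolerance = 1e-12)
  expect_equal(ff2$dihedrals$p[2], 2L)
  expect_equal(ff2$dihedrals$phi0[2], pi)
  expect_error(add_fit_term(ff2, quad, 2, 180), "already present")
})

test_that("nested fits never increase the RMSE", {
  m <- fixture_molecule("butane")
  quad <- c(0L, 1L, 2L, 3L)
  gen <- data.frame(A = c(6, 2), p = c(3, 1), phi0 = c(0, pi))
  ff <- toy_ff(m)
  scan0 <- synthetic_scan(quad, gen, n_points = 19, mol = m)
  ref <- dihedral_scan(quad, scan0$angles,
                       mm_scan(m, ff, scan0) +
                         torsion_energy(scan0$angles * pi / 180, gen),
                       scan0$geometries)
  rmse <- numeric(0)
  ffi <- ff
  for (term in list(c(2, 90), c(3, 0), c(1, 180))) {
    ffi <- add_fit_term(ffi, quad, term[1], term[2])
    ffi <- fit_dihedral(ffi, quad, m, ref)
    rmse <- c(rmse, attr(ffi, "fit_report")$rmse)
  }
  expect_true(all(diff(rmse) <= 1e-9))
  expect_lt(rmse[3], 1e-9)   # full basis reproduces the target
})
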