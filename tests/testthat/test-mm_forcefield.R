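test_that("cosine torsion series evaluates exactly", {
  one <- data.frame(A = 1, p = 1, phi0 = 0)
  expect_equal(torsion_energy(pi, one), 0)
  expect_equal(torsion_energy(0, one), 2)

  set.seed(20)
  terms <- data.frame(A = rnorm(3), p = c(1L, 2L, 3L), phi0 = runif(3, -pi, pi))
  phis <- runif(100, -2 * pi, 2 * pi)
  brute <- vapply(phis, function(f) {
    s <- 0
    for (i in 1:3) s <- s + terms$A[i] * (1 + cos(terms$p[i] * f - terms$phi0[i]))
    s
  }, numeric(1))
  expect_equal(torsion_energy(phis, terms), brute, tolerance = 1e-12)

  # single-term periodicity: V(phi) = V(phi + 2 pi / p)
  for (p in 1:3) {
    tm <- data.frame(A = 1.7, p = p, phi0 = 0.4)
    expect_equal(torsion_energy(phis + 2 * pi / p, tm), torsion_energy(phis, tm),
                 tolerance = 1e-12)
  }
})

test_that("MM evaluation: bonded zeros, LJ closed form, missing-parameter error", {
  m <- fixture_molecule("water")
  ff <- forcefield_from_geometry(m)   # terms at the current geometry
  ev <- evaluate_mm(m, ff)
  expect_equal(unname(ev$energy[["bond"]] + ev$energy[["angle"]]), 0)
  expect_equal(unname(ev$energy[["total"]]), 0)

  # isolated LJ pair at the well minimum
  sig <- 3.2; eps <- 0.8
  pair <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0)))
  ffp <- forcefield(2, sigma = sig, epsilon = eps)
  expect_equal(unname(evaluate_mm(pair, ffp)$energy[["lj"]]), -eps,
               tolerance = 1e-12)

  ff_missing <- forcefield(3)
  expect_error(evaluate_mm(m, ff_missing), "missing bond parameter")
})

test_that("analytic MM gradient matches finite differences", {
  set.seed(21)
  m <- fixture_molecule("butane")
  ff <- toy_ff(m, charges = rnorm(14, 0, 0.05))
  ff <- add_dihedral_term(ff, c(0, 1, 2, 3), 6, 3, 0)
  m$coordinates <- m$coordinates + matrix(rnorm(42, 0, 0.05), 14, 3)
  ev <- evaluate_mm(m, ff)
  gfd <- fd_gradient(function(x) {
    mm <- m; mm$coordinates <- x
    evaluate_mm(mm, ff, gradient = FALSE)$energy[["total"]]
  }, m$coordinates, h = 1e-5)
  expect_lt(max(abs(ev$gradient - gfd)), 1e-6)
})

test_that("MM energy is invariant under rigid motion; forces and torques vanish", {
  set.seed(22)
  m <- fixture_molecule("butane")
  ff <- toy_ff(m, charges = rnorm(14, 0, 0.05))
  ff <- add_dihedral_term(ff, c(0, 1, 2, 3), 6, 3, 0)
  e0 <- evaluate_mm(m, ff)
  R <- ffcraft:::rotation_matrix(c(1, 2, 2) / 3, 0.9)
  m2 <- m
  m2$coordinates <- m$coordinates %*% t(R) +
    matrix(c(3, -1, 7), 14, 3, byrow = TRUE)
  e1 <- evaluate_mm(m2, ff)
  expect_equal(unname(e1$energy[["total"]]), unname(e0$energy[["total"]]),
               tolerance = 1e-8)
  expect_lt(max(abs(colSums(e0$gradient))), 1e-8)
  torque <- colSums(t(vapply(seq_len(14), function(a) {
    ffcraft:::vcross(m$coordinates[a, ], e0$gradient[a, ])
  }, numeric(3))))
  expect_lt(max(abs(torque)), 1e-8)
})

test_that("Seminario recovers a diatomic spring constant exactly", {
  k <- 987.6
  x <- rbind(c(0, 0, 0), c(1.2, 0.5, -0.3))
  u <- (x[2, ] - x[1, ]); u <- u / sqrt(sum(u^2))
  blk <- k * (u %o% u)
  H <- rbind(cbind(blk, -blk), cbind(-blk, blk))
  m <- perceive_bonds(molecule(c("O", "O"), x))
  sp <- seminario_parameters(m, H)
  expect_equal(sp$bonds$k, k, tolerance = 1e-10)
  expect_equal(sp$bonds$r0, sqrt(sum((x[2, ] - x[1, ])^2)))

  # invariance under rigid rotation of the molecule + Hessian pair
  R <- ffcraft:::rotation_matrix(c(0.6, 0, 0.8), 0.7)
  m2 <- m; m2$coordinates <- x %*% t(R)
  Rbig <- kronecker(diag(2), R)
  sp2 <- seminario_parameters(m2, Rbig %*% H %*% t(Rbig))
  expect_equal(sp2$bonds$k, sp$bonds$k, tolerance = 1e-9)
})

test_that("Seminario handles zero and non-symmetric Hessians", {
  m <- fixture_molecule("water")
  H0 <- matrix(0, 9, 9)
  sp <- seminario_parameters(m, H0)
  expect_true(all(sp$bonds$k == 0))
  expect_true(all(sp$angles$k == 0))
  H0[1, 2] <- 5
  expect_error(seminario_parameters(m, H0), "symmetric")
})

test_that("Seminario angle construction matches its independent re-evaluation", {
  # independent implementation of the classic perpendicular-projection formula,
  # evaluated against a finite-difference Hessian of a harmonic-angle potential
  m <- fixture_molecule("water")
  ka <- 345
  th0 <- ffcraft:::angle_value(m$coordinates, 1, 0, 2)
  pot <- function(x) 0.5 * ka * (ffcraft:::angle_value(x, 1, 0, 2) - th0)^2
  h <- 1e-4
  H <- matrix(0, 9, 9)
  for (col in 1:9) {
    a <- (col - 1) %/% 3 + 1; d <- (col - 1) %% 3 + 1
    xp <- m$coordinates; xp[a, d] <- xp[a, d] + h
    xm <- m$coordinates; xm[a, d] <- xm[a, d] - h
    H[, col] <- as.vector(t(fd_gradient(pot, xp, h) - fd_gradient(pot, xm, h))) /
      (2 * h)
  }
  H <- (H + t(H)) / 2
  got <- seminario_parameters(m, H)$angles$k

  x <- m$coordinates
  arm <- function(a, b, u_p) {
    K <- -(H[(3 * a + 1):(3 * a + 3), (3 * b + 1):(3 * b + 3)])
    K <- (K + t(K)) / 2
    e <- eigen(K, symmetric = TRUE)
    sum((x[a + 1, ] - x[b + 1, ])^2) *
      sum(e$values * abs(as.vector(u_p %*% e$vectors)))
  }
  u1 <- x[2, ] - x[1, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- x[3, ] - x[1, ]; u2 <- u2 / sqrt(sum(u2^2))
  un <- ffcraft:::vcross(u2, u1); un <- un / sqrt(sum(un^2))
  expected <- 1 / (1 / arm(1L, 0L, ffcraft:::vcross(un, u1)) +
                     1 / arm(2L, 0L, ffcraft:::vcross(u2, un)))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("GROMACS export round-trips and conserves charge", {
  set.seed(23)
  m <- fixture_molecule("butane")
  q <- rnorm(14, 0, 0.1); q <- q - mean(q)   # neutral molecule
  ff <- toy_ff(m, charges = q)
  ff <- add_dihedral_term(ff, c(0, 1, 2, 3), 6, 3, 0)
  ff <- add_dihedral_term(ff, c(0, 1, 2, 3), 1.5, 1, pi)
  base <- file.path(withr::local_tempdir(), "mol")
  write_gromacs(m, ff, base)

  itp <- readLines(paste0(base, ".itp"))
  ff2 <- ffcraft:::read_gromacs(base)
  expect_equal(sum(ff2$charges), m$charge, tolerance = 1e-6)
  expect_equal(ff2$charges, ff$charges, tolerance = 1e-4)
  expect_equal(ff2$bonds$k, ff$bonds$k, tolerance = 1e-8)
  expect_equal(ff2$bonds$r0, ff$bonds$r0, tolerance = 1e-8)
  expect_equal(ff2$angles$theta0, ff$angles$theta0, tolerance = 1e-6)
  expect_equal(ff2$dihedrals$A, ff$dihedrals$A, tolerance = 1e-6)
  expect_equal(ff2$dihedrals$p, ff$dihedrals$p)
  expect_equal(ff2$sigma, ff$sigma, tolerance = 1e-5)

  # one funct-9 line per cosine term on the quad
  dsec <- grep("\\[ dihedrals \\]", itp)
  nine <- grep("^\\s*1\\s+2\\s+3\\s+4\\s+9", itp)
  expect_equal(length(nine), 2L)
})

test_that("OBC2 generalized Born obeys its closed-form limits", {
  eps <- 78.5
  ke <- ffcraft:::.coulomb_ke

  ion <- molecule("Cl", matrix(0, 1, 3))
  expect_equal(gb_obc2_energy(ion, charges = -1, radii = 2.0, dielectric = eps),
               -(1 - 1 / eps) * ke / (2 * 2.0), tolerance = 1e-12)

  w <- fixture_molecule("water")
  expect_equal(gb_obc2_energy(w, charges = c(0, 0, 0)), 0)
  expect_error(gb_obc2_energy(w, charges = c(1, 0, 0), dielectric = -1),
               "dielectric")

  # two distant unit charges: Born self terms + screened Coulomb cross term
  two <- molecule(c("Na", "Na"), rbind(c(0, 0, 0), c(100, 0, 0)))
  e <- gb_obc2_energy(two, charges = c(1, 1), radii = 1.5, dielectric = eps)
  selfs <- 2 * (-(1 - 1 / eps) * ke / (2 * 1.5))
  cross <- -(1 - 1 / eps) * ke / 100
  expect_equal(e, selfs + cross, tolerance = 1e-3)
  expect_equal(e, selfs, tolerance = 0.016)   # selfs dominate at 100 A
})
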