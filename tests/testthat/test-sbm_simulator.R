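# Potential evaluation, analytic forces and Langevin dynamics.

test_that("dihedral restraint has the printed closed form and periodicity", {
  phi0 <- 0.7
  expect_equal(dihedralRestraint(phi0, phi0), 0)
  expect_equal(dihedralRestraint(phi0 + pi, phi0), 3)  # [1-cos pi] + (1/2)[1-cos 3pi]
  grid <- seq(-pi, pi, length.out = 5000)
  expect_equal(dihedralRestraint(grid, phi0),
               dihedralRestraint(grid + 2 * pi, phi0))
  # grid-search oracle: minimum at phi0 (mod 2 pi)
  vals <- dihedralRestraint(grid, phi0)
  expect_lt(abs(grid[which.min(vals)] - phi0), 2 * pi / 4999 + 1e-9)
  expect_true(all(vals >= 0))
})

test_that("native conformation zeroes bonded terms and scores -epsC per contact", {
  fx <- fix_two_domain()
  e <- sbmEnergy(fx$s, fx$topo, fx$params)
  expect_equal(e[["bond"]], 0, tolerance = 1e-12)
  expect_equal(e[["angle"]], 0, tolerance = 1e-12)
  expect_equal(e[["planar"]], 0, tolerance = 1e-12)
  expect_equal(e[["dihedral_bb"]] + e[["dihedral_sc"]], 0, tolerance = 1e-10)
  expect_equal(e[["contact"]],
               -nrow(contacts(fx$topo)) * fx$params@epsContact,
               tolerance = 1e-9)
  expect_gte(e[["noncontact"]], 0)
  expect_equal(e[["total"]], sum(e[1:7]), tolerance = 1e-9)
})

test_that("single contact pair reproduces the printed 12-6 form by hand", {
  topo <- bond_only_topology()
  topo@bonds <- topo@bonds[0, ]
  topo@contacts <- data.frame(i = 1L, j = 2L, sigma = 3.0)
  topo@exclusions <- matrix(integer(0), 0, 2)
  p <- ForceFieldParameters(epsContact = 2.5, epsNC = 0)
  at <- function(r) sbmEnergy(matrix(c(0, 0, 0, r, 0, 0), 2, 3,
                                     byrow = TRUE), topo, p)[["contact"]]
  expect_equal(at(3), -2.5, tolerance = 1e-12)
  r <- 3 * 2^(1 / 6)
  hand <- 2.5 * ((3 / r)^12 - 2 * (3 / r)^6)
  expect_equal(at(r), hand, tolerance = 1e-12)
  # linearity in the prefactor
  p2 <- ForceFieldParameters(epsContact = 5.0, epsNC = 0)
  e2 <- sbmEnergy(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE), topo, p2)
  e1 <- sbmEnergy(matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE), topo, p)
  expect_equal(e2[["contact"]], 2 * e1[["contact"]], tolerance = 1e-12)
  expect_equal(e2[["noncontact"]], e1[["noncontact"]])
})

test_that("analytic forces match central differences and obey Newton's third law", {
  fx <- fix_two_domain()
  set.seed(42)
  for (rep in 1:3) {
    x <- coords(fx$s) + matrix(stats::rnorm(3 * nAtoms(fx$s), sd = 0.08),
                               ncol = 3)
    Fa <- sbmForces(x, fx$topo, fx$params)
    expect_lt(max(abs(Fa - fd_forces(x, fx$topo, fx$params))), 1e-4)
    expect_lt(max(abs(colSums(Fa))), 1e-9)
  }
  # bonded contributions vanish at the native minimum
  p_bonded <- ForceFieldParameters(epsContact = 0, epsNC = 0)
  expect_lt(max(abs(sbmForces(fx$s, fx$topo, p_bonded))), 1e-8)
  expect_error(sbmForces(matrix(0, 3, 3), fx$topo, fx$params), "atoms")
})

test_that("Langevin runs are reproducible and record at the configured cadence", {
  fx <- fix_two_domain()
  cfg <- SimulationConfig(temperature = 0.4, nSteps = 5000,
                          recordEvery = 500, seed = 7)
  t1 <- runLangevin(fx$s, fx$topo, fx$params, cfg)
  t2 <- runLangevin(fx$s, fx$topo, fx$params, cfg)
  expect_equal(nFrames(t1), 10)
  expect_identical(frames(t1), frames(t2))
  expect_identical(energies(t1), energies(t2))
  expect_equal(energies(t1)$step, seq(500, 5000, by = 500))
  t3 <- runLangevin(fx$s, fx$topo, fx$params,
                    SimulationConfig(temperature = 0.4, nSteps = 5000,
                                     recordEvery = 500, seed = 8))
  expect_false(identical(frames(t1), frames(t3)))
})

test_that("quenched dynamics at a near-zero temperature stays at the native minimum", {
  fx <- fix_two_domain()
  cfg <- SimulationConfig(temperature = 1e-4, nSteps = 20000,
                          recordEvery = 1000, seed = 1)
  tr <- runLangevin(fx$s, fx$topo, fx$params, cfg)
  expect_lt(rmsd(frames(tr)[[nFrames(tr)]], coords(fx$s)), 0.1)
})

test_that("harmonic-bond sampling matches equipartition and the analytic variance", {
  s <- two_atom_structure()
  topo <- bond_only_topology()
  p <- ForceFieldParameters()
  cfg <- SimulationConfig(temperature = 0.5, nSteps = 400000,
                          recordEvery = 400, seed = 1)
  tr <- runLangevin(s, topo, p, cfg)
  burn <- -(1:100)
  ke <- mean(energies(tr)$kinetic[burn])
  expect_equal(ke / 6, cfg@temperature / 2, tolerance = 0.05)
  blen <- vapply(frames(tr), function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
                 numeric(1))
  expect_equal(stats::var(blen[burn]), cfg@temperature / (2 * p@epsR),
               tolerance = 0.05)
})

test_that("divergent simulations abort with the step index", {
  s <- two_atom_structure(d = 0.02)  # absurdly compressed bond
  topo <- bond_only_topology(r0 = 1.5)
  cfg <- SimulationConfig(temperature = 0.5, dt = 0.5, nSteps = 1000,
                          recordEvery = 100, seed = 1, guard = 100)
  expect_error(runLangevin(s, topo, ForceFieldParameters(), cfg),
               "diverged at step")
})
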