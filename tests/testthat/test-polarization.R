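test_that("uniform external field passes through unchanged without charges", {
  m <- ethaneMol()
  E <- fieldAtAtoms(m, rep(0, 8), externalField = c(0.01, 0, 0))
  expect_equal(E, matrix(rep(c(0.01, 0, 0), each = 8), 8, 3))
})

test_that("1-2 pairs contribute no field and 1-4 exactly half", {
  ## bonded diatomic: mutual fields fully excluded
  m <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                bonds = cbind(1, 2, 1), units = "bohr")
  E <- fieldAtAtoms(m, c(0.5, -0.5))
  expect_equal(E, matrix(0, 2, 3))

  ## linear 4-chain, unit charge on atom 4 only: field at atom 1 is half
  ## of the bare Coulomb value
  chain <- Molecule(rep("C", 4),
                    cbind(c(0, 2, 4, 6), 0, 0),
                    bonds = cbind(1:3, 2:4, 1), units = "bohr")
  E <- fieldAtAtoms(chain, c(0, 0, 0, 1))
  bare <- -1 / 6^2
  expect_equal(E[1, ], c(0.5 * bare, 0, 0))
})

test_that("an unbonded unit charge gives the bare Coulomb field", {
  m <- Molecule(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)), units = "bohr")
  suppressWarnings(E <- fieldAtAtoms(m, c(0, 1)))
  expect_equal(E[1, ], c(-0.25, 0, 0))   # 1/r^2 at 2 bohr, toward the charge
  expect_equal(E[2, ], c(0, 0, 0))       # the other atom is uncharged
})

test_that("coincident atoms raise a singularity error", {
  m <- Molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)))
  suppressWarnings(expect_error(fieldAtAtoms(m, c(1, 1)), "singular"))
})

test_that("induced dipoles are the elementwise scalar product", {
  expect_equal(inducedDipoles(10, matrix(c(0.01, 0, 0), 1)),
               matrix(c(0.1, 0, 0), 1))
  expect_equal(inducedDipoles(0, matrix(c(0.3, 0.1, 0), 1)),
               matrix(0, 1, 3))
  set.seed(3)
  a <- runif(5, 0, 10); E <- matrix(rnorm(15), 5)
  expect_equal(inducedDipoles(a, 2 * E), 2 * inducedDipoles(a, E))
  expect_error(inducedDipoles(-1, matrix(0, 1, 3)), ">= 0")
})

test_that("ESP reproduces the Coulomb and dipole kernels", {
  m <- Molecule("H", matrix(0, 1, 3), units = "bohr")
  expect_equal(espAtPoints(m, 1, NULL, matrix(c(1, 0, 0), 1)), 1.0)
  ## dipole 0.1 au along x, observer at (2,0,0): 0.1 * 2 / 8 = 0.025
  expect_equal(espAtPoints(m, NULL, matrix(c(0.1, 0, 0), 1),
                           matrix(c(2, 0, 0), 1)), 0.025)
})

test_that("ESP is a superposition of charge and dipole contributions", {
  set.seed(7)
  for (rep in 1:5) {
    mol <- randomMolecule(6)
    q <- rnorm(6); mu <- matrix(rnorm(18), 6) * 0.1
    pts <- matrix(rnorm(30, sd = 8), 10)
    both <- espAtPoints(mol, q, mu, pts)
    expect_equal(both, espAtPoints(mol, q, NULL, pts) +
                   espAtPoints(mol, NULL, mu, pts), tolerance = 1e-12)
  }
})

test_that("a grid point on top of an atom raises a singularity error", {
  m <- Molecule("H", matrix(0, 1, 3), units = "bohr")
  expect_error(espAtPoints(m, 1, NULL, matrix(0, 1, 3)), "singular")
})

test_that("brute-force pairwise oracle reproduces fields and ESP", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(2:20, 1)
    mol <- randomMolecule(n, ring = rep %% 3 == 0)
    q <- rnorm(n)
    Eext <- rnorm(3) * 0.01
    E <- fieldAtAtoms(mol, q, externalField = Eext)
    expect_equal(E, fieldOracle(mol, q, Eext), tolerance = 1e-12)
    mu <- inducedDipoles(runif(n, 0, 10), E)
    pts <- matrix(rnorm(3 * 15, sd = 10), 15)
    expect_equal(espAtPoints(mol, q, mu, pts),
                 espOracle(mol, q, mu, pts), tolerance = 1e-12)
  }
})

test_that("fields, dipoles and ESP are rotationally equivariant", {
  set.seed(17)
  mol <- randomMolecule(8)
  q <- rnorm(8); a <- runif(8, 0, 8)
  pts <- matrix(rnorm(3 * 12, sd = 9), 12)
  Eext <- c(0.01, -0.003, 0.002)
  R <- rotationMatrix(c(0.2, -1, 0.7), 2.2)
  molR <- rotateMolecule(mol, R)
  E0 <- fieldAtAtoms(mol, q, externalField = Eext)
  E1 <- fieldAtAtoms(molR, q, externalField = drop(R %*% Eext))
  expect_equal(E1, E0 %*% t(R), tolerance = 1e-10)
  mu0 <- inducedDipoles(a, E0); mu1 <- inducedDipoles(a, E1)
  v0 <- espAtPoints(mol, q, mu0, pts)
  v1 <- espAtPoints(molR, q, mu1, pts %*% t(R))
  expect_equal(v1, v0, tolerance = 1e-10)
  expect_equal(rrmse(v1, v0 + 0.01), rrmse(v0, v0 + 0.01), tolerance = 1e-9)
})

test_that("model ESP is linear in the charge vector", {
  set.seed(23)
  mol <- ethanolMol()
  a <- assignPolarizabilities(mol, defaultTruthTyping())$alphas
  grid <- generateMskGrid(mol, tinyGrid())
  A <- respDesignMatrix(mol, a, grid)
  for (rep in 1:4) {
    q <- rnorm(nAtoms(mol))
    expect_equal(modelEsp(mol, q, a, grid), drop(A %*% q),
                 tolerance = 1e-12)
  }
})

test_that("RRMSE matches its defining limits and the hand example", {
  v <- c(0.3, -0.2, 0.5)
  expect_equal(rrmse(v, v), 0)
  expect_equal(rrmse(rep(0, 3), v), 1)
  expect_equal(rrmse(c(0, 0), c(3, 4)), 1)
  expect_equal(rrmse(c(3, 0), c(3, 4)), 0.8)
  expect_error(rrmse(c(1, 1), c(0, 0)), "undefined")
})

test_that("molecular dipole follows the charge and induced terms", {
  m <- Molecule(c("H", "H"), rbind(c(1, 0, 0), c(-1, 0, 0)), units = "bohr")
  suppressWarnings({
    expect_equal(molecularDipole(m, c(0.5, -0.5)), c(1, 0, 0))
    expect_equal(molecularDipole(m, c(0, 0),
                                 rbind(c(0.1, 0, 0), c(0, 0, 0))),
                 c(0.1, 0, 0))
  })
  expect_equal(dipoleAuToDebye(), 2.541746473)
})

test_that("neutral-molecule dipole is translation invariant", {
  set.seed(31)
  mol <- methanolMol()
  q <- rnorm(6); q <- q - mean(q)
  mu0 <- molecularDipole(mol, q)
  shifted <- Molecule(atomElements(mol), atomCoords(mol) +
                        matrix(rep(c(5, -3, 2), each = 6), 6), units = "bohr",
                      bonds = bondMatrix(mol))
  expect_equal(molecularDipole(shifted, q), mu0, tolerance = 1e-12)
})

test_that("molecular polarizability is the permutation-invariant sum", {
  expect_equal(molecularPolarizability(numeric(0)), 0)
  expect_equal(molecularPolarizability(c(1.2, 0.3, 0.3)), 1.8)
  set.seed(37)
  a <- runif(10, 0, 10)
  expect_equal(molecularPolarizability(sample(a)),
               molecularPolarizability(a))
  expect_error(molecularPolarizability(c(1, -2)), ">= 0")
})
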