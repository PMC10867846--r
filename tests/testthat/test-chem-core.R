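test_that("scaling factors follow bonded path length on hand molecules", {
  eth <- ethaneMol()
  f <- scalingMatrix(scalingFactors(eth))
  expect_equal(f[3, 1], 0)      # H on C1 to C1: 1-2
  expect_equal(f[3, 2], 0)      # H on C1 to C2: 1-3
  expect_equal(f[3, 6], 0.5)    # H on C1 to H on C2: 1-4
  expect_equal(f[3, 4], 0)      # geminal hydrogens: 1-3

  but <- butaneMol()
  fb <- scalingMatrix(scalingFactors(but))
  expect_equal(fb[1, 5], 1)     # C1 to H on C4: path length 4, unscaled
  expect_equal(fb[1, 4], 0.5)   # C1-C4: 1-4
  expect_true(isSymmetric(fb))
})

test_that("scaling factors agree with a BFS oracle on random graphs", {
  set.seed(11)
  for (rep in 1:12) {
    mol <- randomMolecule(sample(4:12, 1), ring = rep %% 2 == 0)
    expect_equal(scalingMatrix(scalingFactors(mol)), bfsScalingOracle(mol))
  }
})

test_that("an atom with no bonds warns and gets factor 1 to everything", {
  mol <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_warning(st <- scalingFactors(mol), "no bonds")
  expect_equal(scalingMatrix(st)[1, 2], 1)
})

test_that("element-scheme polarizability assignment is a plain lookup", {
  ts <- polTypeSet("element", c("C", "H", "O"), c(1.0, 2.0, 3.0))
  got <- assignPolarizabilities(methanolMol(), ts)
  expect_equal(got$alphas, c(1, 3, 2, 2, 2, 2))
  expect_error(
    assignPolarizabilities(
      Molecule("N", matrix(0, 1, 3)), ts), "no polarizability type")
})

test_that("pattern scheme applies last-match-wins hierarchy", {
  ts <- polTypeSet("pattern",
                   c("[#6]", "[#1]", "[#8]", "[#6X4]-[#8]", "[#8H1]"),
                   c(1, 2, 3, 10, 30))
  got <- assignPolarizabilities(methanolMol(), ts)
  expect_equal(got$alphas[1], 10)   # alcohol carbon: specific entry wins
  expect_equal(got$alphas[2], 30)   # hydroxyl oxygen
  expect_equal(got$alphas[3:6], rep(2, 4))
})

test_that("benzene gets one value per element under the element scheme", {
  bz <- makeToySet(1)
  bz <- bz[[which(vapply(bz, function(m) m@name, "") == "benzene")[1]]]
  ts <- polTypeSet("element", c("C", "H"), c(5, 1))
  a <- assignPolarizabilities(bz, ts)$alphas
  expect_equal(unique(a[atomElements(bz) == "C"]), 5)
  expect_equal(unique(a[atomElements(bz) == "H"]), 1)
})

test_that("symmetry classes group topologically equivalent atoms", {
  methane <- Molecule(c("C", rep("H", 4)),
                      rbind(c(0, 0, 0), diag(3) * 0.9, c(0.5, 0.5, 0.5)),
                      bonds = cbind(1, 2:5, 1))
  cl <- symmetryClasses(methane)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[2:5])), 1)

  eth <- ethanolMol()
  cl <- symmetryClasses(eth)
  el <- atomElements(eth)
  hydroxylH <- which(el == "H")[6]
  methylH <- 4:6; methyleneH <- 7:8
  expect_equal(length(unique(cl[methylH])), 1)
  expect_equal(length(unique(cl[methyleneH])), 1)
  expect_false(cl[hydroxylH] %in% cl[c(methylH, methyleneH)])
  expect_false(cl[methylH[1]] == cl[methyleneH[1]])

  bz <- makeToySet(1)
  bz <- bz[[which(vapply(bz, function(m) m@name, "") == "benzene")[1]]]
  expect_equal(length(unique(symmetryClasses(bz))), 2)
})

test_that("symmetry classes are invariant under atom reordering", {
  set.seed(5)
  mol <- ethanolMol()
  cl <- symmetryClasses(mol)
  for (rep in 1:5) {
    perm <- sample(nAtoms(mol))
    inv <- order(perm)
    b <- bondMatrix(mol)
    permuted <- Molecule(atomElements(mol)[perm],
                         atomCoords(mol)[perm, ], units = "bohr",
                         bonds = cbind(inv[b[, 1]], inv[b[, 2]], b[, 3]))
    clp <- symmetryClasses(permuted)
    ## same partition: equal labels iff equal labels in the original
    expect_equal(outer(clp, clp, "=="), outer(cl[perm], cl[perm], "=="))
  }
})

test_that("bond type matrix is antisymmetric with zero column sums", {
  co <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
                 bonds = cbind(1, 2, 3))
  tab <- bondTypeTable("CO", "[#6]", "[#8]", 3)
  Tm <- bondTypeMatrix(co, tab)
  expect_equal(unname(Tm), rbind(1, -1))

  ## homonuclear bond with identical environments cancels to zero
  eth <- ethaneMol()
  tabE <- bondTypeTable(c("cc", "ch"), c("[#6]", "[#6]"),
                        c("[#6]", "[#1]"), c(1, 1))
  Tm <- bondTypeMatrix(eth, tabE)
  expect_equal(unname(Tm[, "cc"]), rep(0, 8))

  ## formaldehyde: hand enumeration gives column sums (0, 0)
  fa <- formaldehydeMol()
  tabF <- bondTypeTable(c("C=O", "C-H"), c("[#6]", "[#6]"),
                        c("[#8]", "[#1]"), c(2, 1))
  Tm <- bondTypeMatrix(fa, tabF)
  expect_equal(unname(colSums(Tm)), c(0, 0))
  expect_equal(unname(Tm[, "C=O"]), c(1, -1, 0, 0))
  expect_equal(unname(Tm[, "C-H"]), c(2, 0, -1, -1))
})

test_that("column sums of T are zero on random molecules", {
  set.seed(21)
  tab <- bondTypeTable(c("any"), "[*]", "[*]", 1)
  for (rep in 1:8) {
    mol <- randomMolecule(sample(3:10, 1), ring = rep %% 2 == 0)
    Tm <- bondTypeMatrix(mol, tab)
    expect_equal(unname(colSums(Tm)), 0)
  }
})

test_that("an unmatched bond names the offending bond", {
  co <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
                 bonds = cbind(1, 2, 3))
  tab <- bondTypeTable("single-co", "[#6]", "[#8]", 1)
  expect_error(bondTypeMatrix(co, tab), "bond 1-2")
})
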