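## shared small synthetic setup: full toy set, coarse grids for speed
toyProblem <- function(noise = 0, seed = 1, spec = tinyGrid()) {
  mols <- makeToySet(seed)
  truth <- makeGroundTruth(mols, noiseSigma = noise, seed = seed)
  confs <- lapply(mols, function(m) {
    r <- synthEspRecords(m, truth, spec)
    list(molecule = m, baseline = r$baseline, differences = r$differences,
         charges = r$charges, alphas = r$alphas)
  })
  list(mols = mols, truth = truth, confs = confs)
}

test_that("typed polarizabilities are recovered exactly from noiseless records", {
  tp <- toyProblem()
  problem <- polFitProblem(tp$confs, polTypeSet("element", c("C", "H", "O", "N")))
  fit <- fitPolarizabilities(problem)
  truthA <- tp$truth@typing@alphas
  expect_lt(max(abs(fit@alphas - truthA) / truthA), 1e-8)
  diag <- attr(fit, "diagnostics")
  expect_lt(max(abs(diag$alphaNelderMead - diag$alphaLinear) /
                  diag$alphaLinear), 1e-6)
})

test_that("all-zero difference records drive alphas to the zero boundary", {
  tp <- toyProblem()
  confs <- lapply(tp$confs[1:8], function(cf) {
    cf$differences <- lapply(cf$differences, function(d)
      ESPRecord(d@grid, rep(0, length(potentials(d))),
                appliedField = appliedField(d), kind = "difference"))
    cf
  })
  skel <- polTypeSet("element", c("C", "H", "O"))
  fit <- fitPolarizabilities(polFitProblem(confs, skel), method = "linear")
  expect_equal(unname(fit@alphas), rep(0, 3), tolerance = 1e-10)
})

test_that("duplicating every conformer leaves the alpha fit unchanged", {
  tp <- toyProblem()
  skel <- polTypeSet("element", c("C", "H", "O", "N"))
  f1 <- fitPolarizabilities(polFitProblem(tp$confs, skel), method = "linear")
  f2 <- fitPolarizabilities(polFitProblem(c(tp$confs, tp$confs), skel),
                            method = "linear")
  expect_equal(f2@alphas, f1@alphas, tolerance = 1e-12)
})

test_that("a type with no matching atoms is an unidentifiable-parameter error", {
  tp <- toyProblem()
  skel <- polTypeSet("element", c("C", "H", "O", "N", "S"))
  expect_error(fitPolarizabilities(polFitProblem(tp$confs, skel)),
               "unidentifiable.*S")
})

test_that("alpha fit is invariant to rigid rotation of a conformer", {
  tp <- toyProblem()
  skel <- polTypeSet("element", c("C", "H", "O", "N"))
  confs <- tp$confs
  R <- rotationMatrix(c(1, 1, 0), 0.9)
  cf <- confs[[3]]
  rotated <- list(
    molecule = rotateMolecule(cf$molecule, R),
    differences = lapply(cf$differences, function(d) {
      g <- new("ESPGrid", points = gridPoints(d@grid) %*% t(R),
               shell = shellIndex(d@grid), spec = d@grid@spec)
      ESPRecord(g, potentials(d),
                appliedField = drop(R %*% appliedField(d)),
                kind = "difference")
    }))
  confs[[3]] <- rotated
  f1 <- fitPolarizabilities(polFitProblem(tp$confs, skel), method = "linear")
  f2 <- fitPolarizabilities(polFitProblem(confs, skel), method = "linear")
  expect_equal(f2@alphas, f1@alphas, tolerance = 1e-9)
})

test_that("alpha recovery error grows monotonically with ESP noise", {
  errs <- vapply(c(1e-5, 1e-4, 1e-3), function(sig) {
    tp <- toyProblem(noise = sig)
    fit <- fitPolarizabilities(
      polFitProblem(tp$confs, polTypeSet("element", c("C", "H", "O", "N"))),
      method = "linear")
    max(abs(fit@alphas - tp$truth@typing@alphas) / tp$truth@typing@alphas)
  }, 1.0)
  expect_true(all(diff(errs) > 0))
  ## roughly linear growth: 100x more noise, error within ~[10x, 1000x]
  expect_gt(errs[3] / errs[1], 10)
})

test_that("unrestrained RESP-dPol recovers the generating charges", {
  tp <- toyProblem(spec = mskGridSpec(nLayers = 3, density = 3))
  for (cf in tp$confs[c(1, 6, 10, 15)]) {
    fit <- fitRespDpol(cf$molecule, cf$baseline, cf$alphas,
                       stages = list(restraintSpec(0, 0.1, "none", 1)))
    expect_lt(max(abs(fittedCharges(fit) - cf$charges)), 1e-7)
    expect_true(fit@converged)
  }
})

test_that("with zero alphas and no restraint the fit equals a plain ESP fit", {
  tp <- toyProblem(spec = mskGridSpec(nLayers = 3, density = 3))
  cf <- tp$confs[[6]]
  mol <- cf$molecule
  n <- nAtoms(mol)
  alphas0 <- rep(0, n)
  grid <- cf$baseline@grid
  V <- modelEsp(mol, cf$charges, alphas0, grid)
  rec <- ESPRecord(grid, V, kind = "baseline")
  fit <- fitRespDpol(mol, rec, alphas0,
                     stages = list(restraintSpec(0, 0.1, "none", 1)))
  ## independent normal-equations oracle with a Lagrange constraint
  pts <- gridPoints(grid)
  xyz <- atomCoords(mol)
  A <- sapply(seq_len(n), function(j)
    1 / sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2)))
  M <- rbind(cbind(2 * crossprod(A), rep(1, n)), c(rep(1, n), 0))
  sol <- solve(M, c(2 * crossprod(A, V), formalCharge(mol)))
  expect_equal(fittedCharges(fit), sol[1:n], tolerance = 1e-9)
})

test_that("the Lagrange constraint pins the charge sum at every setting", {
  tp <- toyProblem(spec = tinyGrid())
  for (cf in tp$confs[c(2, 8, 12, 17, 20)]) {
    fit <- fitRespDpol(cf$molecule, cf$baseline, cf$alphas)
    expect_lt(abs(sum(fittedCharges(fit)) -
                    formalCharge(cf$molecule)), 1e-10)
  }
})

test_that("stage 2 enforces exact charge equality within symmetry classes", {
  tp <- toyProblem(spec = mskGridSpec(nLayers = 3, density = 3))
  cf <- tp$confs[[6]]    # a methanol conformer: one methyl group
  expect_equal(cf$molecule@name, "methanol")
  fit <- fitRespDpol(cf$molecule, cf$baseline, cf$alphas)
  q <- fittedCharges(fit)
  classes <- symmetryClasses(cf$molecule)
  refit <- fit@details$refitAtoms
  expect_gt(length(refit), 0)
  for (cl in unique(classes[refit])) {
    members <- refit[classes[refit] == cl]
    expect_equal(diff(range(q[members])), 0)
  }
})

test_that("the restrained objective never increases across reweighting", {
  tp <- toyProblem(spec = tinyGrid())
  for (cf in tp$confs[c(4, 9, 14)]) {
    fit <- fitRespDpol(cf$molecule, cf$baseline, cf$alphas)
    tr1 <- fit@details$stage1$trace
    expect_true(all(diff(tr1) <= 1e-10 * pmax(1, tr1[-length(tr1)])))
    if (!is.null(fit@details$stage2)) {
      tr2 <- fit@details$stage2$trace
      expect_true(all(diff(tr2) <= 1e-10 * pmax(1, tr2[-length(tr2)])))
    }
  }
})

test_that("a baseline record with a field is rejected", {
  tp <- toyProblem()
  cf <- tp$confs[[1]]
  expect_error(fitRespDpol(cf$molecule, cf$differences[[1]], cf$alphas),
               "baseline")
})

## BCC training set built from the toy molecules with known true BCCs
bccSetup <- function(spec = tinyGrid()) {
  tp <- toyProblem(spec = spec)
  tab <- toyBccTable()
  Btrue <- c("c4-c3" = 0.02, "c4-c4" = 0, "c-o" = 0.08, "c=o" = 0.15,
             "c-n" = 0.06, "ar-cc" = 0, "ar-ch" = -0.01, "c-h" = -0.03,
             "o-h" = 0.20, "n-h" = 0.12)
  first <- tp$confs[!duplicated(vapply(tp$confs,
                                       function(cf) cf$molecule@name, ""))]
  training <- lapply(first, function(cf) {
    Tm <- bondTypeMatrix(cf$molecule, tab)
    qpre <- cf$charges - drop(Tm %*% Btrue[colnames(Tm)])
    list(molecule = cf$molecule, precharges = qpre, baseline = cf$baseline)
  })
  list(tp = tp, tab = tab, Btrue = Btrue, training = training)
}

test_that("true BCCs are recovered on all supported bond types", {
  s <- bccSetup()
  fit <- fitBccs(s$training, s$tab, s$tp$truth@typing)
  B <- bccValues(fit)
  sup <- fit@covered
  expect_lt(max(abs(B[sup] - s$Btrue[names(B)][sup])), 1e-7)
  expect_equal(unname(B[!sup]), rep(0, sum(!sup)))
})

test_that("a zero-BCC ground truth fits to zero", {
  s <- bccSetup()
  training0 <- lapply(s$tp$confs[!duplicated(vapply(
    s$tp$confs, function(cf) cf$molecule@name, ""))], function(cf)
      list(molecule = cf$molecule, precharges = cf$charges,
           baseline = cf$baseline))
  fit <- fitBccs(training0, s$tab, s$tp$truth@typing)
  expect_lt(max(abs(bccValues(fit))), 1e-8)
})

test_that("fitted corrections conserve every molecule's total charge", {
  s <- bccSetup()
  fit <- fitBccs(s$training, s$tab, s$tp$truth@typing)
  for (entry in s$training) {
    q <- assignAm1BccDpol(entry$molecule, entry$precharges, s$tab, fit)
    expect_equal(sum(q), sum(entry$precharges), tolerance = 1e-12)
  }
})

test_that("AM1-BCC-dPol assignment applies the bond-type transfers", {
  co <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
                 bonds = cbind(1, 2, 3))
  tab <- bondTypeTable("CO", "[#6]", "[#8]", 3)
  q <- assignAm1BccDpol(co, c(0.2, -0.2), tab, c(CO = 0.1))
  expect_equal(q, c(0.3, -0.3))
  ## zero corrections reproduce the precharges
  q0 <- assignAm1BccDpol(co, c(0.2, -0.2), tab, c(CO = 0))
  expect_equal(q0, c(0.2, -0.2))
  ## a matched type without a value is an error
  expect_error(assignAm1BccDpol(co, c(0.2, -0.2), tab, c(XX = 0.1)),
               "no BCC value")
})

test_that("assignment conserves charge for random molecules and BCCs", {
  set.seed(41)
  tab <- bondTypeTable("any", "[*]", "[*]", 1)
  for (rep in 1:6) {
    mol <- randomMolecule(sample(3:9, 1))
    pre <- rnorm(nAtoms(mol))
    q <- assignAm1BccDpol(mol, pre, tab, c(any = rnorm(1)))
    expect_equal(sum(q), sum(pre), tolerance = 1e-12)
  }
})
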