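#' @include AllClasses.R AllGenerics.R polarization.R grid.R
NULL

## ---- idealized geometry templates (Angstrom) ----------------------------

tetrahedralDirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

## three substituent directions around an sp3 atom whose fourth bond points
## along +x; phase rotates them about x (staggering)
methylDirs <- function(phase = 0) {
  ct <- -1 / 3; st <- 2 * sqrt(2) / 3
  phi <- (c(0, 120, 240) + phase) * pi / 180
  cbind(rep(ct, 3), st * cos(phi), st * sin(phi))
}

toyGeometries <- function() {
  CH <- 1.09; CC <- 1.54; CO <- 1.43; OH <- 0.96; CN <- 1.47; NH <- 1.01
  geoms <- list()

  h <- tetrahedralDirs() * CH
  geoms$methane <- list(
    elements = c("C", "H", "H", "H", "H"),
    xyz = rbind(c(0, 0, 0), h),
    bonds = cbind(1L, 2:5, 1L), charge = 0L, atomCharges = NULL)

  c2 <- c(CC, 0, 0)
  h1 <- methylDirs(0) * CH                  # on C1, pointing away from C2
  h2 <- sweep(-methylDirs(0) * CH, 2, c2, "+")  # staggered, away from C1
  geoms$ethane <- list(
    elements = c("C", "C", rep("H", 6)),
    xyz = rbind(c(0, 0, 0), c2, h1, h2),
    bonds = rbind(c(1L, 2L, 1L),
                  cbind(1L, 3:5, 1L), cbind(2L, 6:8, 1L)),
    charge = 0L, atomCharges = NULL)

  o <- c(CO, 0, 0)
  hC <- methylDirs(0) * CH                  # methyl H's; C-O along +x
  hO <- o + OH * c(0.317, 0.948, 0)         # C-O-H about 108.5 deg
  geoms$methanol <- list(
    elements = c("C", "O", "H", "H", "H", "H"),
    xyz = rbind(c(0, 0, 0), o, hC, hO),
    bonds = rbind(c(1L, 2L, 1L), cbind(1L, 3:5, 1L), c(2L, 6L, 1L)),
    charge = 0L, atomCharges = NULL)

  n <- c(CN, 0, 0)
  hN <- sweep(-methylDirs(0)[1:2, ] * NH, 2, n, "+")  # pyramidal NH2
  geoms$methylamine <- list(
    elements = c("C", "N", "H", "H", "H", "H", "H"),
    xyz = rbind(c(0, 0, 0), n, methylDirs(0) * CH, hN),
    bonds = rbind(c(1L, 2L, 1L), cbind(1L, 3:5, 1L), cbind(2L, 6:7, 1L)),
    charge = 0L, atomCharges = NULL)

  ## acetamide CH3-C(=O)-NH2, heavy atoms in the xy plane
  cc <- c(1.52, 0, 0)
  oC <- cc + 1.23 * c(0.5, sqrt(3) / 2, 0)
  nC <- cc + 1.34 * c(0.5, -sqrt(3) / 2, 0)
  hN1 <- nC + NH * c(sqrt(3) / 2, -0.5, 0)
  hN2 <- nC + NH * c(0, -1, 0)
  geoms$acetamide <- list(
    elements = c("C", "C", "O", "N", "H", "H", "H", "H", "H"),
    xyz = rbind(c(0, 0, 0), cc, oC, nC, methylDirs(30) * CH, hN1, hN2),
    bonds = rbind(c(1L, 2L, 1L), c(2L, 3L, 2L), c(2L, 4L, 1L),
                  cbind(1L, 5:7, 1L), cbind(4L, 8:9, 1L)),
    charge = 0L, atomCharges = NULL)

  ## acetate anion CH3-COO(-)
  o1 <- cc + 1.26 * c(0.5, sqrt(3) / 2, 0)
  o2 <- cc + 1.26 * c(0.5, -sqrt(3) / 2, 0)
  geoms$acetate <- list(
    elements = c("C", "C", "O", "O", "H", "H", "H"),
    xyz = rbind(c(0, 0, 0), cc, o1, o2, methylDirs(30) * CH),
    bonds = rbind(c(1L, 2L, 1L), c(2L, 3L, 2L), c(2L, 4L, 1L),
                  cbind(1L, 5:7, 1L)),
    charge = -1L, atomCharges = c(0L, 0L, 0L, -1L, 0L, 0L, 0L))

  geoms$ammonium <- list(
    elements = c("N", "H", "H", "H", "H"),
    xyz = rbind(c(0, 0, 0), tetrahedralDirs() * 1.03),
    bonds = cbind(1L, 2:5, 1L), charge = 1L,
    atomCharges = c(1L, 0L, 0L, 0L, 0L))

  ## benzene: aromatic ring + in-plane hydrogens
  ang <- (0:5) * pi / 3
  cRing <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hRing <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  ringBonds <- cbind(1:6, c(2:6, 1L), AROMATIC_ORDER)
  geoms$benzene <- list(
    elements = c(rep("C", 6), rep("H", 6)),
    xyz = rbind(cRing, hRing),
    bonds = rbind(ringBonds, cbind(1:6, 7:12, 1L)),
    charge = 0L, atomCharges = NULL)

  geoms
}

coordRmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Deterministic CHON toy molecule set with conformers
#'
#' Eight idealized small molecules spanning the trained chemistry (alkanes,
#' an alcohol, an amine, an amide, a carboxylate anion, an ammonium cation,
#' an aromatic), each in 2-4 conformers. Conformers beyond the first are
#' smooth seeded distortions of the template geometry; all conformer pairs
#' of a molecule differ by at least 0.5 Angstrom coordinate RMSD, mirroring
#' the distinctness required of the training conformations. Identical seeds
#' give bit-identical coordinates.
#'
#' @param seed integer seed
#' @return flat list of \linkS4class{Molecule}s; each carries its molecule
#'   \code{name} and a \code{conformerId} like "methanol/2"
#' @export
makeToySet <- function(seed = 1L) {
  geoms <- toyGeometries()
  nConf <- c(2L, 3L, 4L, 3L, 2L, 3L, 2L, 4L)
  out <- list()
  for (gi in seq_along(geoms)) {
    g <- geoms[[gi]]
    nm <- names(geoms)[gi]
    confs <- list(g$xyz)
    for (ci in seq_len(nConf[gi] - 1L)) {
      attempt <- 0L
      repeat {
        set.seed((seed %% 100000L) * 10000L + gi * 1000L + ci * 10L + attempt)
        cand <- g$xyz + matrix(stats::rnorm(length(g$xyz), sd = 0.45),
                               nrow(g$xyz), 3)
        if (all(vapply(confs, function(x) coordRmsd(cand, x) >= 0.5, TRUE)))
          break
        attempt <- attempt + 1L
      }
      confs[[ci + 1L]] <- cand
    }
    for (ci in seq_along(confs))
      out[[length(out) + 1L]] <- Molecule(
        g$elements, confs[[ci]], g$bonds, formalCharge = g$charge,
        units = "angstrom", name = nm,
        conformerId = paste0(nm, "/", ci),
        atomFormalCharges = g$atomCharges)
  }
  out
}

#' Default element-scheme ground-truth polarizabilities
#'
#' Realistic atomic polarizabilities for the CHON scope (bohr^3), of the
#' magnitude typical for Applequist-style element parameters.
#'
#' @return a \linkS4class{PolarizabilityTypeSet}
#' @export
defaultTruthTyping <- function() {
  polTypeSet("element", c("C", "H", "O", "N"), c(9.4, 2.7, 5.4, 7.4))
}

#' Build a ground-truth model over a molecule set
#'
#' Draws seeded per-molecule true charges (shared across conformers of the
#' same molecule, summing exactly to the formal charge) and pairs them with
#' true typed polarizabilities. Charges are drawn per topological symmetry
#' class, so equivalent atoms carry equal true charges, as in any physically
#' sensible charge model; this keeps stage-2 symmetry equivalencing
#' consistent with the ground truth. The resulting model generates every
#' synthetic ESP record, so all fitting procedures can be checked by
#' parameter recovery.
#'
#' @param molecules list of \linkS4class{Molecule}s (e.g.
#'   \code{\link{makeToySet}()})
#' @param typing true polarizabilities; default
#'   \code{\link{defaultTruthTyping}()}
#' @param noiseSigma i.i.d. Gaussian ESP noise, hartree/e (0 = exact)
#' @param seed integer seed
#' @return a \linkS4class{GroundTruthModel}
#' @export
makeGroundTruth <- function(molecules, typing = defaultTruthTyping(),
                            noiseSigma = 0, seed = 1L) {
  names <- unique(vapply(molecules, function(m) m@name, ""))
  charges <- list()
  for (i in seq_along(names)) {
    mol <- molecules[[match(names[i], vapply(molecules, function(m) m@name, ""))]]
    set.seed((seed %% 100000L) * 1000L + i)
    classes <- symmetryClasses(mol)
    perClass <- stats::runif(max(classes), -0.5, 0.5)
    raw <- perClass[classes]
    charges[[names[i]]] <- raw - (sum(raw) - formalCharge(mol)) / nAtoms(mol)
  }
  new("GroundTruthModel", typing = typing, charges = charges,
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Synthesize baseline and field-perturbed ESP records for one conformer
#'
#' Emulates the reference-data protocol: a baseline ESP on an MSK-style
#' grid, plus six ESPs under uniform external fields of 0.01 au along
#' +x, -x, +y, -y, +z, -z, reported as difference records (perturbed minus
#' baseline). All records come from the package's own direct-polarization
#' model with the ground truth's charges and polarizabilities; optional
#' Gaussian noise is added after differencing.
#'
#' @param molecule a \linkS4class{Molecule} from the truth's set
#' @param truth a \linkS4class{GroundTruthModel} covering the molecule
#' @param gridSpec grid specification; default \code{\link{mskGridSpec}()}
#' @param fieldMagnitude inducing field strength, au
#' @return list with \code{baseline} (\linkS4class{ESPRecord}),
#'   \code{differences} (list of six records), \code{charges},
#'   \code{alphas}, and \code{grid}
#' @export
synthEspRecords <- function(molecule, truth, gridSpec = mskGridSpec(),
                            fieldMagnitude = 0.01) {
  charges <- truth@charges[[molecule@name]]
  if (is.null(charges))
    stop("ground truth has no charges for molecule ", molecule@name,
         call. = FALSE)
  alphas <- assignPolarizabilities(molecule, truth@typing)$alphas
  grid <- generateMskGrid(molecule, gridSpec)
  scaling <- scalingFactors(molecule)
  base <- modelEsp(molecule, charges, alphas, grid, scaling = scaling)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * fieldMagnitude
  noisy <- function(v, tag) {
    if (truth@noiseSigma <= 0) return(v)
    set.seed((truth@seed %% 100000L) * 100L +
               sum(utf8ToInt(paste0(molecule@conformerId, tag))) %% 100000L)
    v + stats::rnorm(length(v), sd = truth@noiseSigma)
  }
  diffs <- vector("list", 6L)
  for (l in seq_len(6L)) {
    pert <- modelEsp(molecule, charges, alphas, grid,
                     externalField = dirs[l, ], scaling = scaling)
    diffs[[l]] <- ESPRecord(grid, noisy(pert - base, l),
                            appliedField = dirs[l, ], kind = "difference")
  }
  list(baseline = ESPRecord(grid, noisy(base, "b"), kind = "baseline"),
       differences = diffs, charges = charges, alphas = alphas, grid = grid)
}

#' Synthetic ideal dipolar-gas time series
#'
#' N independent molecules, each carrying a point dipole of fixed magnitude
#' with a fresh uniformly random orientation every frame, in a constant
#' box. The closed-form static dielectric constant of this independent-
#' rotor model, D = 1 + 4 pi N mu0^2 / (3 V k_B T), is returned alongside
#' the series as the analytic target for the fluctuation estimator.
#'
#' @param nMolecules number of independent dipoles
#' @param dipoleMagnitude mu0 per molecule, e*bohr
#' @param temperature K
#' @param nFrames number of frames
#' @param volume box volume, bohr^3
#' @param seed integer seed (fixed seed gives a bit-identical series)
#' @return list with \code{series} (\linkS4class{LiquidSeries}) and
#'   \code{analyticD}
#' @export
synthDipoleSeries <- function(nMolecules, dipoleMagnitude, temperature,
                              nFrames, volume, seed = 1L) {
  stopifnot(nMolecules > 0, dipoleMagnitude >= 0, temperature > 0,
            nFrames > 0, volume > 0)
  set.seed(seed %% .Machine$integer.max)
  n <- nFrames * nMolecules
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  ux <- s * cos(phi); uy <- s * sin(phi)
  grp <- rep(seq_len(nFrames), each = nMolecules)
  mu <- dipoleMagnitude * cbind(
    rowsum(ux, grp), rowsum(uy, grp), rowsum(z, grp))
  series <- LiquidSeries(mu, volume, temperature)
  analyticD <- 1 + 4 * pi * nMolecules * dipoleMagnitude^2 /
    (3 * volume * KBOLTZ_HARTREE * temperature)
  list(series = series, analyticD = analyticD)
}

#' Frozen toy box for the high-frequency dielectric cross-check
#'
#' Places rigid three-atom polar molecules (bent, water-like topology with
#' O and two H) at seeded random positions and orientations in a cubic box
#' and returns them as one composite structure with per-atom charges and
#' element-typed polarizabilities, for finite-difference polarization-
#' response tests.
#'
#' @param nMolecules number of molecules
#' @param boxLength cube edge, bohr
#' @param typing polarizability truth; default
#'   \code{\link{defaultTruthTyping}()}
#' @param seed integer seed
#' @return list with \code{molecule} (one \linkS4class{Molecule} holding
#'   all atoms), \code{charges}, \code{alphas}, \code{volume} (bohr^3)
#' @export
synthFrozenBox <- function(nMolecules = 50L, boxLength = 60,
                           typing = defaultTruthTyping(), seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  ## template: O at origin, two H at 104.5 deg, 0.96 Angstrom (in bohr)
  rOH <- 0.96 * BOHR_PER_ANGSTROM
  a <- 104.5 / 2 * pi / 180
  template <- rbind(c(0, 0, 0),
                    rOH * c(sin(a), cos(a), 0),
                    rOH * c(-sin(a), cos(a), 0))
  elements <- character(0); xyz <- NULL; bonds <- NULL
  for (m in seq_len(nMolecules)) {
    ## random rotation from a QR decomposition of a Gaussian matrix
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::runif(3, 0, boxLength)
    pos <- template %*% t(Q) + matrix(shift, 3, 3, byrow = TRUE)
    base <- length(elements)
    elements <- c(elements, "O", "H", "H")
    xyz <- rbind(xyz, pos)
    bonds <- rbind(bonds, c(base + 1L, base + 2L, 1L),
                   c(base + 1L, base + 3L, 1L))
  }
  mol <- Molecule(elements, xyz, bonds, units = "bohr", name = "toybox")
  charges <- rep(c(-0.8, 0.4, 0.4), nMolecules)
  alphas <- assignPolarizabilities(mol, typing)$alphas
  list(molecule = mol, charges = charges, alphas = alphas,
       volume = boxLength^3)
}

#' Finite-difference high-frequency dielectric of the direct model
#'
#' Numerical cross-check of the analytic eps_inf: applies a uniform field
#' to a frozen configuration, computes the induced polarization with the
#' package's own field and dipole operations, and returns
#' 1 + 4 pi (P(E) - P(0)) / E along the field axis.
#'
#' @param box a list from \code{\link{synthFrozenBox}} (molecule, charges,
#'   alphas, volume)
#' @param fieldMagnitude probe field, au
#' @param axis 1, 2 or 3
#' @return unitless eps_inf estimate
#' @export
epsilonInfinityFD <- function(box, fieldMagnitude = 1e-3, axis = 1L) {
  eVec <- c(0, 0, 0); eVec[axis] <- fieldMagnitude
  scal <- scalingFactors(box$molecule)
  p0 <- colSums(inducedDipoles(box$alphas,
    fieldAtAtoms(box$molecule, box$charges, scal))) / box$volume
  p1 <- colSums(inducedDipoles(box$alphas,
    fieldAtAtoms(box$molecule, box$charges, scal, eVec))) / box$volume
  1 + 4 * pi * (p1[axis] - p0[axis]) / fieldMagnitude
}

#' Write a full synthetic fixture tree
#'
#' Emits, under \code{dir}: one SDF per conformer, grid/potential file
#' pairs with JSON sidecars for the baseline and six difference records,
#' and \code{truth.json} with the generating charges and polarizabilities.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @param gridSpec grid specification (default full MSK spec)
#' @return invisibly, the directory
#' @export
writeSyntheticFixtures <- function(dir, seed = 1L, gridSpec = mskGridSpec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mols <- makeToySet(seed)
  truth <- makeGroundTruth(mols, seed = seed)
  for (mol in mols) {
    stem <- file.path(dir, gsub("/", "_c", mol@conformerId))
    writeMoleculeSDF(mol, paste0(stem, ".sdf"))
    rec <- synthEspRecords(mol, truth, gridSpec)
    writeEspRecord(rec$baseline, paste0(stem, "_baseline"))
    for (l in seq_along(rec$differences))
      writeEspRecord(rec$differences[[l]], paste0(stem, "_diff", l))
  }
  jsonlite::write_json(
    list(seed = seed,
         typing = list(scheme = truth@typing@scheme,
                       match = truth@typing@matchers,
                       alpha_bohr3 = truth@typing@alphas),
         charges = truth@charges),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
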