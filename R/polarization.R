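#' @include AllClasses.R AllGenerics.R chem-core.R
NULL

#' Electric field at atom sites from permanent charges and an external field
#'
#' Direct polarization approximation: the field at atom j is the uniform
#' external field plus the scaled Coulomb fields of the other permanent
#' charges, E_j = E_ext + sum_k f_jk q_k (r_j - r_k) / |r_j - r_k|^3.
#' Induced dipoles never contribute. All quantities in atomic units.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param charges per-atom charges, e
#' @param scaling a \linkS4class{ScalingTable}; computed from the molecule
#'   if omitted
#' @param externalField uniform field 3-vector, au
#' @return nAtoms x 3 matrix of fields, au
#' @export
#' @examples
#' co <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
#'                bonds = cbind(1, 2, 3), units = "bohr")
#' # bonded (1-2) pair: charge fields excluded, only the external field
#' fieldAtAtoms(co, c(0.5, -0.5), externalField = c(0.01, 0, 0))
fieldAtAtoms <- function(molecule, charges, scaling = NULL,
                         externalField = c(0, 0, 0)) {
  n <- nAtoms(molecule)
  stopifnot(length(charges) == n)
  if (is.null(scaling)) scaling <- scalingFactors(molecule)
  f <- scalingMatrix(scaling)
  xyz <- atomCoords(molecule)
  E <- matrix(rep(as.numeric(externalField), each = n), n, 3)
  if (n < 2) return(E)
  dx <- outer(xyz[, 1], xyz[, 1], "-")             # r_j - r_k per axis
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  diag(r2) <- 1
  off <- !diag(TRUE, n)
  if (any(r2[off] < 1e-20))
    stop("coincident atom positions: Coulomb field is singular",
         call. = FALSE)
  inv_r3 <- 1 / (r2 * sqrt(r2))
  w <- f * inv_r3
  diag(w) <- 0
  qk <- as.numeric(charges)
  E[, 1] <- E[, 1] + (w * dx) %*% qk
  E[, 2] <- E[, 2] + (w * dy) %*% qk
  E[, 3] <- E[, 3] + (w * dz) %*% qk
  E
}

#' Induced dipoles from polarizabilities and local fields
#'
#' Pure isotropic linear response: mu_j = alpha_j * E_j, elementwise.
#'
#' @param alphas per-atom polarizabilities, bohr^3 (all >= 0)
#' @param fields nAtoms x 3 matrix of fields, au
#' @return nAtoms x 3 matrix of induced dipoles, au (e*bohr)
#' @export
inducedDipoles <- function(alphas, fields) {
  fields <- as.matrix(fields)
  stopifnot(length(alphas) == nrow(fields), ncol(fields) == 3)
  if (any(alphas < 0))
    stop("polarizabilities must be >= 0", call. = FALSE)
  fields * as.numeric(alphas)
}

#' Electrostatic potential of charges plus induced dipoles at grid points
#'
#' V_i = sum_j q_j / |r_ij| + sum_j mu_j . r_ij / |r_ij|^3, with r_ij the
#' vector from atom j to grid point i. No damping and no pair scaling:
#' intramolecular scaling applies to atom-site fields only, never at
#' observer points.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param charges per-atom charges, e (NULL for dipoles only)
#' @param dipoles nAtoms x 3 induced-dipole matrix, au (NULL for none)
#' @param grid an \linkS4class{ESPGrid} or nPoints x 3 matrix in bohr
#' @return numeric potentials, hartree/e
#' @export
#' @examples
#' m <- Molecule("H", matrix(0, 1, 3), units = "bohr")
#' pt <- matrix(c(1, 0, 0), 1)
#' espAtPoints(m, charges = 1, dipoles = NULL, grid = pt)  # 1 hartree/e
espAtPoints <- function(molecule, charges, dipoles, grid) {
  pts <- if (is(grid, "ESPGrid")) gridPoints(grid) else as.matrix(grid)
  n <- nAtoms(molecule)
  xyz <- atomCoords(molecule)
  V <- numeric(nrow(pts))
  for (j in seq_len(n)) {
    rx <- pts[, 1] - xyz[j, 1]
    ry <- pts[, 2] - xyz[j, 2]
    rz <- pts[, 3] - xyz[j, 3]
    r2 <- rx^2 + ry^2 + rz^2
    if (any(r2 < 1e-16))
      stop(sprintf("grid point coincides with atom %d: singular ESP", j),
           call. = FALSE)
    inv_r <- 1 / sqrt(r2)
    if (!is.null(charges) && charges[j] != 0)
      V <- V + charges[j] * inv_r
    if (!is.null(dipoles)) {
      mu <- dipoles[j, ]
      if (any(mu != 0))
        V <- V + (mu[1] * rx + mu[2] * ry + mu[3] * rz) * inv_r^3
    }
  }
  V
}

#' Model ESP of a polarized molecule
#'
#' Convenience wrapper: computes the scaled permanent-charge fields at the
#' atoms (plus any external field), the direct-approximation induced
#' dipoles, and the resulting potential at the grid points.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param charges per-atom charges, e
#' @param alphas per-atom polarizabilities, bohr^3
#' @param grid an \linkS4class{ESPGrid} or point matrix (bohr)
#' @param externalField uniform external field, au
#' @param scaling optional precomputed \linkS4class{ScalingTable}
#' @return numeric potentials, hartree/e
#' @export
modelEsp <- function(molecule, charges, alphas, grid,
                     externalField = c(0, 0, 0), scaling = NULL) {
  E <- fieldAtAtoms(molecule, charges, scaling, externalField)
  mu <- inducedDipoles(alphas, E)
  espAtPoints(molecule, charges, mu, grid)
}

#' Relative root-mean-square error between model and reference ESPs
#'
#' sqrt( sum_i (V_ref_i - V_model_i)^2 / sum_i V_ref_i^2 ). Unitless;
#' 0 for a perfect model, 1 for a model that predicts zero everywhere.
#'
#' @param model model potentials
#' @param reference reference potentials (not identically zero)
#' @return unitless fraction
#' @export
#' @examples
#' rrmse(c(3, 0), c(3, 4))  # 0.8
rrmse <- function(model, reference) {
  stopifnot(length(model) == length(reference), length(model) > 0)
  denom <- sum(reference^2)
  if (denom == 0)
    stop("reference ESP is identically zero: RRMSE undefined", call. = FALSE)
  sqrt(sum((reference - model)^2) / denom)
}

#' Molecular dipole moment from charges and induced dipoles
#'
#' mu = sum_j q_j r_j + sum_j mu_ind_j. For charged species the permanent
#' term is origin-dependent; the center of nuclear charge is used as origin
#' by convention (a no-op for neutral molecules, whose dipole is
#' origin-independent).
#'
#' @param molecule a \linkS4class{Molecule}
#' @param charges per-atom charges, e
#' @param dipoles nAtoms x 3 induced dipoles, au (NULL for none)
#' @return 3-vector in au; multiply by \code{dipoleAuToDebye()} for Debye
#' @export
molecularDipole <- function(molecule, charges, dipoles = NULL) {
  xyz <- atomCoords(molecule)
  if (formalCharge(molecule) != 0L) {
    z <- unname(ATOMIC_NUMBERS[atomElements(molecule)])
    origin <- colSums(xyz * z) / sum(z)
    xyz <- sweep(xyz, 2, origin)
  }
  mu <- colSums(xyz * as.numeric(charges))
  if (!is.null(dipoles)) mu <- mu + colSums(as.matrix(dipoles))
  unname(mu)
}

#' Conversion factor from atomic-unit dipole to Debye
#' @return scalar: Debye per e*bohr
#' @export
dipoleAuToDebye <- function() DEBYE_PER_AU

#' Molecular polarizability under the direct approximation
#'
#' Induced dipoles feel only permanent charges and external fields, so the
#' molecular polarizability is the plain sum of the atomic values.
#'
#' @param alphas per-atom polarizabilities, bohr^3
#' @return scalar, bohr^3; divide by \code{BOHR_PER_ANGSTROM^3} via
#'   \code{polBohr3ToAngstrom3()} for Angstrom^3
#' @export
molecularPolarizability <- function(alphas) {
  if (length(alphas) && any(alphas < 0))
    stop("polarizabilities must be >= 0", call. = FALSE)
  sum(alphas)
}

#' Conversion factor from bohr^3 to Angstrom^3
#' @return scalar
#' @export
polBohr3ToAngstrom3 <- function() ANGSTROM_PER_BOHR^3
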