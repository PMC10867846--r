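#' @import methods
NULL

## Bond order encoding: 1, 2, 3 for single/double/triple; 4 for aromatic.
AROMATIC_ORDER <- 4L

#' Molecule: atoms, coordinates, bonds, formal charge
#'
#' The topology object every computation hangs on. Coordinates are stored in
#' bohr internally; constructors and readers accept Angstrom (the default I/O
#' unit). Bond orders are integers 1, 2, 3, with 4 denoting an aromatic bond
#' (a distinct order class for bond typing).
#'
#' @slot name molecule identity label, shared across conformers
#' @slot conformerId opaque conformer label
#' @slot elements character vector of element symbols
#' @slot coordinates numeric matrix (nAtoms x 3), bohr
#' @slot bonds integer matrix (nBonds x 3): from, to, order
#' @slot formalCharge integer total molecular charge (e)
#' @slot atomFormalCharges integer per-atom formal charges (e); informational,
#'   must sum to \code{formalCharge} when any is nonzero
#'
#' @exportClass Molecule
setClass("Molecule",
  representation(
    name = "character",
    conformerId = "character",
    elements = "character",
    coordinates = "matrix",
    bonds = "matrix",
    formalCharge = "integer",
    atomFormalCharges = "integer"
  ),
  prototype(
    name = "", conformerId = "",
    elements = character(0),
    coordinates = matrix(numeric(0), ncol = 3),
    bonds = matrix(integer(0), ncol = 3),
    formalCharge = 0L,
    atomFormalCharges = integer(0)
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msgs <- character(0)
  if (nrow(object@coordinates) != n || ncol(object@coordinates) != 3)
    msgs <- c(msgs, "coordinates must be an nAtoms x 3 matrix")
  if (any(!is.finite(object@coordinates)))
    msgs <- c(msgs, "coordinates must be finite")
  b <- object@bonds
  if (ncol(b) != 3)
    msgs <- c(msgs, "bonds must have three columns (from, to, order)")
  if (nrow(b) > 0) {
    if (any(b[, 1:2] < 1) || any(b[, 1:2] > n))
      msgs <- c(msgs, "bond indices out of range")
    if (any(b[, 1] == b[, 2]))
      msgs <- c(msgs, "self-loop bond")
    if (!all(b[, 3] %in% c(1L, 2L, 3L, 4L)))
      msgs <- c(msgs, "bond orders must be 1, 2, 3 or 4 (aromatic)")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate bond")
  }
  if (length(object@atomFormalCharges) != n)
    msgs <- c(msgs, "atomFormalCharges length must equal atom count")
  else if (any(object@atomFormalCharges != 0L) &&
           sum(object@atomFormalCharges) != object@formalCharge)
    msgs <- c(msgs, "atomFormalCharges must sum to formalCharge")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule
#'
#' @param elements character vector of element symbols
#' @param coordinates nAtoms x 3 numeric matrix
#' @param bonds matrix or data.frame with columns from, to, order; order may
#'   be 1, 2, 3, 4 or the string "ar" for aromatic
#' @param formalCharge integer total charge (e)
#' @param units units of \code{coordinates}: "angstrom" (default) or "bohr"
#' @param name,conformerId identity labels
#' @param atomFormalCharges optional integer per-atom formal charges
#' @return A \linkS4class{Molecule}.
#' @export
#' @examples
#' co <- Molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
#'                bonds = cbind(1, 2, 3))
#' nAtoms(co)
Molecule <- function(elements, coordinates, bonds = NULL, formalCharge = 0L,
                     units = c("angstrom", "bohr"),
                     name = "", conformerId = "",
                     atomFormalCharges = NULL) {
  units <- match.arg(units)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (units == "angstrom") coordinates <- coordinates * BOHR_PER_ANGSTROM
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 3)
  bonds <- as.matrix(as.data.frame(bonds))
  if (nrow(bonds) > 0 && is.character(bonds)) {
    ord <- bonds[, 3]
    ord[ord %in% c("ar", "aromatic")] <- "4"
    bonds <- cbind(as.integer(bonds[, 1]), as.integer(bonds[, 2]),
                   as.integer(ord))
  }
  storage.mode(bonds) <- "integer"
  dimnames(bonds) <- NULL
  dimnames(coordinates) <- NULL
  if (is.null(atomFormalCharges))
    atomFormalCharges <- integer(length(elements))
  new("Molecule", name = name, conformerId = conformerId,
      elements = as.character(elements), coordinates = coordinates,
      bonds = bonds, formalCharge = as.integer(formalCharge),
      atomFormalCharges = as.integer(atomFormalCharges))
}

#' Pairwise intramolecular scaling factors
#'
#' Symmetric table of factors f in {0, 0.5, 1} attenuating
#' charge-polarizability interactions by shortest bonded path length:
#' 0 for 1-2 and 1-3 pairs, 0.5 for 1-4, 1 otherwise. The diagonal is unused
#' and kept at 0.
#'
#' @slot factors numeric nAtoms x nAtoms matrix
#' @exportClass ScalingTable
setClass("ScalingTable", representation(factors = "matrix"))

setValidity("ScalingTable", function(object) {
  f <- object@factors
  if (nrow(f) != ncol(f)) return("factors must be square")
  if (!isTRUE(all.equal(f, t(f)))) return("factors must be symmetric")
  if (!all(f %in% c(0, 0.5, 1))) return("factors must be in {0, 0.5, 1}")
  TRUE
})

#' Typed polarizability set
#'
#' Maps atoms to isotropic polarizabilities (bohr^3) via either an element
#' lookup or an ordered list of SMARTS patterns with last-match-wins
#' (SMIRNOFF hierarchy) semantics. A "skeleton" set has NA values and is
#' filled in by \code{\link{fitPolarizabilities}}.
#'
#' @slot scheme "element" or "pattern"
#' @slot matchers element symbols or SMARTS strings, in hierarchy order
#' @slot alphas polarizability per matcher, bohr^3 (NA for skeletons)
#' @exportClass PolarizabilityTypeSet
setClass("PolarizabilityTypeSet",
  representation(scheme = "character", matchers = "character",
                 alphas = "numeric"))

setValidity("PolarizabilityTypeSet", function(object) {
  msgs <- character(0)
  if (!object@scheme %in% c("element", "pattern"))
    msgs <- c(msgs, "scheme must be 'element' or 'pattern'")
  if (length(object@matchers) != length(object@alphas))
    msgs <- c(msgs, "matchers and alphas must have equal length")
  if (any(!is.na(object@alphas) & object@alphas < 0))
    msgs <- c(msgs, "alphas must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PolarizabilityTypeSet
#'
#' @param scheme "element" or "pattern"
#' @param matchers element symbols or SMARTS strings (ordered; for patterns
#'   the last matching entry wins)
#' @param alphas polarizabilities in bohr^3; NA for a skeleton to be fitted
#' @return A \linkS4class{PolarizabilityTypeSet}.
#' @export
#' @examples
#' polTypeSet("element", c("C", "H", "O", "N"), c(9.6, 2.6, 4.8, 7.0))
polTypeSet <- function(scheme, matchers, alphas = rep(NA_real_, length(matchers))) {
  new("PolarizabilityTypeSet", scheme = scheme,
      matchers = as.character(matchers), alphas = as.numeric(alphas))
}

#' Bond-type table for bond charge corrections
#'
#' Ordered bond-type definitions: two atom-environment SMARTS patterns and a
#' bond order (1, 2, 3, or 4 = aromatic). Each bond is assigned to the first
#' matching type; orientation (which end matches the first pattern) sets the
#' sign of the charge transfer.
#'
#' @slot defs data.frame with columns name, smarts1, smarts2, order
#' @exportClass BondTypeTable
setClass("BondTypeTable", representation(defs = "data.frame"))

setValidity("BondTypeTable", function(object) {
  need <- c("name", "smarts1", "smarts2", "order")
  if (!all(need %in% names(object@defs)))
    return("defs must have columns name, smarts1, smarts2, order")
  if (anyDuplicated(object@defs$name)) return("duplicate bond type names")
  TRUE
})

#' Construct a BondTypeTable
#'
#' @param name character vector of type labels
#' @param smarts1,smarts2 atom-environment patterns for the two bond ends
#' @param order bond order per type (1, 2, 3, 4, or "ar")
#' @return A \linkS4class{BondTypeTable}.
#' @export
bondTypeTable <- function(name, smarts1, smarts2, order) {
  order <- as.character(order)
  order[order %in% c("ar", "aromatic")] <- "4"
  new("BondTypeTable", defs = data.frame(
    name = as.character(name), smarts1 = as.character(smarts1),
    smarts2 = as.character(smarts2), order = as.integer(order),
    stringsAsFactors = FALSE))
}

#' ESP sampling grid
#'
#' Merz-Singh-Kollman style shells of points outside the scaled van der Waals
#' surface of a molecule. Points are stored in bohr; grid files use Angstrom.
#'
#' @slot points numeric nPoints x 3 matrix, bohr
#' @slot shell integer shell index per point (1-based, innermost first)
#' @slot spec list describing how the grid was built (nLayers, density,
#'   spacing, innerScale, radiusSet)
#' @exportClass ESPGrid
setClass("ESPGrid",
  representation(points = "matrix", shell = "integer", spec = "list"),
  prototype(points = matrix(numeric(0), ncol = 3), shell = integer(0),
            spec = list()))

setValidity("ESPGrid", function(object) {
  if (ncol(object@points) != 3) return("points must have 3 columns")
  if (length(object@shell) != nrow(object@points))
    return("shell length must equal point count")
  if (any(!is.finite(object@points))) return("points must be finite")
  TRUE
})

#' ESP record: grid, potentials, applied field
#'
#' Holds potential values (hartree/e) on an \linkS4class{ESPGrid}, together
#' with the uniform external field (au) under which they were computed.
#' Baseline records carry a zero field; difference records hold
#' field-perturbed minus baseline values and reference the inducing field.
#'
#' @slot grid the sampling grid
#' @slot values potential per grid point, hartree/e
#' @slot appliedField external field 3-vector, au
#' @slot kind "baseline" or "difference"
#' @exportClass ESPRecord
setClass("ESPRecord",
  representation(grid = "ESPGrid", values = "numeric",
                 appliedField = "numeric", kind = "character"))

setValidity("ESPRecord", function(object) {
  msgs <- character(0)
  if (length(object@values) != nrow(object@grid@points))
    msgs <- c(msgs, "values length must equal grid point count")
  if (length(object@appliedField) != 3)
    msgs <- c(msgs, "appliedField must be a 3-vector")
  if (!object@kind %in% c("baseline", "difference"))
    msgs <- c(msgs, "kind must be 'baseline' or 'difference'")
  if (object@kind == "baseline" && any(object@appliedField != 0))
    msgs <- c(msgs, "baseline records must have zero applied field")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ESPRecord
#' @param grid an \linkS4class{ESPGrid}
#' @param values potentials, hartree/e
#' @param appliedField external field, au (zero for baseline)
#' @param kind "baseline" or "difference"
#' @return An \linkS4class{ESPRecord}.
#' @export
ESPRecord <- function(grid, values, appliedField = c(0, 0, 0),
                      kind = c("baseline", "difference")) {
  kind <- match.arg(kind)
  new("ESPRecord", grid = grid, values = as.numeric(values),
      appliedField = as.numeric(appliedField), kind = kind)
}

#' Charge-fit result
#'
#' @slot charges fitted per-atom charges, e
#' @slot lagrange value of the Lagrange multiplier enforcing total charge
#' @slot iterations restraint-reweighting iterations used
#' @slot converged logical convergence flag
#' @slot objective final chi-squared (ESP residual plus restraint penalty)
#' @slot details list of per-stage diagnostics
#' @exportClass ChargeFitResult
setClass("ChargeFitResult",
  representation(charges = "numeric", lagrange = "numeric",
                 iterations = "integer", converged = "logical",
                 objective = "numeric", details = "list"))

#' BCC-fit result
#'
#' @slot values fitted bond charge corrections B per type, e (named)
#' @slot covered logical per type: had nonzero support in training
#' @slot objective final summed chi-squared
#' @exportClass BCCFitResult
setClass("BCCFitResult",
  representation(values = "numeric", covered = "logical",
                 objective = "numeric"))

#' Liquid-phase time series
#'
#' Per-frame total dipole and box volume from a condensed-phase trajectory,
#' plus the metadata needed by the density and dielectric estimators.
#'
#' @slot dipoles nFrames x 3 matrix of total box dipoles, e*bohr
#' @slot volumes per-frame box volume, bohr^3
#' @slot temperature K
#' @slot totalMass total system mass, g/mol
#' @slot alphasTotal sum of atomic polarizabilities over the box, bohr^3
#' @exportClass LiquidSeries
setClass("LiquidSeries",
  representation(dipoles = "matrix", volumes = "numeric",
                 temperature = "numeric", totalMass = "numeric",
                 alphasTotal = "numeric"))

setValidity("LiquidSeries", function(object) {
  msgs <- character(0)
  if (ncol(object@dipoles) != 3) msgs <- c(msgs, "dipoles must be n x 3")
  if (length(object@volumes) != nrow(object@dipoles))
    msgs <- c(msgs, "volumes length must equal frame count")
  if (any(object@volumes <= 0)) msgs <- c(msgs, "volumes must be positive")
  if (object@temperature < 0) msgs <- c(msgs, "temperature must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LiquidSeries
#'
#' @param dipoles nFrames x 3 total dipole matrix, e*bohr
#' @param volumes per-frame volumes, bohr^3 (recycled if length 1)
#' @param temperature K
#' @param totalMass g/mol over all molecules in the box
#' @param alphasTotal sum of atomic polarizabilities in the box, bohr^3
#' @return A \linkS4class{LiquidSeries}.
#' @export
LiquidSeries <- function(dipoles, volumes, temperature, totalMass = 0,
                         alphasTotal = 0) {
  dipoles <- as.matrix(dipoles)
  storage.mode(dipoles) <- "double"
  dimnames(dipoles) <- NULL
  volumes <- rep_len(as.numeric(volumes), nrow(dipoles))
  new("LiquidSeries", dipoles = dipoles, volumes = volumes,
      temperature = as.numeric(temperature), totalMass = as.numeric(totalMass),
      alphasTotal = as.numeric(alphasTotal))
}

#' Synthetic ground-truth model
#'
#' The emulator standing in for quantum-chemistry reference data: a typing
#' scheme with true polarizabilities, true per-molecule charges, and an
#' optional i.i.d. Gaussian noise level applied to emitted ESP values.
#'
#' @slot typing a \linkS4class{PolarizabilityTypeSet} with true values
#' @slot charges named list: molecule name -> per-atom charges (e)
#' @slot noiseSigma ESP noise standard deviation, hartree/e
#' @slot seed integer RNG seed for reproducibility
#' @exportClass GroundTruthModel
setClass("GroundTruthModel",
  representation(typing = "PolarizabilityTypeSet", charges = "list",
                 noiseSigma = "numeric", seed = "integer"))
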